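wavelength_nm,deg_0,deg_30,deg_60,deg_90,deg_120,deg_150,deg_180,deg_210,deg_240,deg_270,deg_300,deg_330
550,0.057,0.680,0.878,0.707,0.517,NaN,NaN,NaN,0.483,0.707,0.876,0.680
628,0.085,0.668,0.727,0.566,0.516,0.512,0.583,0.558,0.488,0.574,0.724,0.670
940,0.135,0.594,0.784,0.751,0.658,0.648,0.649,0.685,0.694,0.744,0.782,0.595
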