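subject,accuracy_pct,kappa,f1,precision_V,precision_A,precision_C,precision_F,recall_V,recall_A,recall_C,recall_F
1,69.42,0.664,0.695,0.732,0.638,0.714,0.695,0.746,0.689,0.641,0.709
2,76.57,0.728,0.766,0.835,0.714,0.726,0.788,0.774,0.809,0.756,0.728
3,86.93,0.842,0.870,0.913,0.823,0.854,0.888,0.846,0.878,0.853,0.901
4,78.36,0.741,0.784,0.836,0.766,0.744,0.790,0.766,0.828,0.784,0.760
5,70.70,0.653,0.708,0.744,0.668,0.734,0.685,0.727,0.709,0.676,0.719
6,78.65,0.746,0.787,0.833,0.802,0.749,0.764,0.774,0.794,0.825,0.759
7,71.26,0.672,0.713,0.766,0.674,0.744,0.669,0.768,0.715,0.662,0.710
8,80.32,0.784,0.803,0.736,0.813,0.871,0.794,0.822,0.785,0.754,0.853
9,79.53,0.768,0.796,0.861,0.739,0.776,0.814,0.773,0.852,0.798,0.758
10,85.19,0.827,0.853,0.914,0.798,0.828,0.868,0.887,0.844,0.896,0.786
Avg,77.69,0.743,0.778,0.817,0.743,0.774,0.775,0.788,0.790,0.765,0.768
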