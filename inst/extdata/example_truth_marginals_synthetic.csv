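index,role,family,loc1,var1,loc2,var2,w1,w2
1,normal,gaussian_mixture,-0.64411790159595328,1.248313705939462,,,1,
2,normal,gaussian_mixture,-0.41646245072493476,0.57683298659921389,,,1,
3,normal,gaussian_mixture,0.33262252051039987,0.40481652448512673,,,1,
4,lognormal,gaussian_mixture,0.65813035941664588,1.0048498635929159,,,1,
5,lognormal,gaussian_mixture,0.38307241926309765,1.4426359521792731,,,1,
6,lognormal,gaussian_mixture,0.46805511113035875,0.27391952495741878,,,1,
7,bimodal,gaussian_mixture,-0.12981020094598145,0.52870803061654381,3.6896029347532981,0.80382044803170871,0.5,0.5
8,bimodal,gaussian_mixture,0.93661300302169681,0.35769855925916355,3.9736637180939294,0.39601224973521149,0.5,0.5
9,outlier,gaussian_mixture,0.39296125199837117,0.78457492691433939,0.99953905103811702,9.5934293768959034,0.90000000000000002,0.10000000000000001
10,outlier,gaussian_mixture,0.10920987565021797,1.3424896904349957,-0.15085897363002904,9.804521614298098,0.90000000000000002,0.10000000000000001
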