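seed,elongation,flatness,least_axis_mm,major_axis_mm,minor_axis_mm,max2d_row_mm,max2d_col_mm,max2d_slice_mm,max3d_mm,mesh_volume_mm3,voxel_volume_mm3,sphericity,surface_area_mm2,surface_volume_ratio
1,0.9569924798494263,0.938799536022271,25.72673888106278,27.403868338141645,26.22529591838535,29.832867780352597,30.479501308256342,30.479501308256342,34.249087579087416,12573.56640625,12800.0,0.9320579767227173,2805.521728515625,0.2231285572052002
2,0.9921444269672257,0.9754086703823254,26.09104892012875,26.748838422670563,26.538710968899395,30.479501308256342,30.4138126514911,30.4138126514911,33.67491648096547,12573.7333984375,12800.0,0.9309791922569275,2808.79736328125,0.22338610887527466
3,0.9757036427409449,0.9558859053170209,25.887395873545053,27.082098113957922,26.424101782856418,29.832867780352597,30.479501308256342,29.832867780352597,34.219877264537345,12574.2080078125,12800.0,0.9308416247367859,2809.283203125,0.2234163135290146
4,0.9764104589348772,0.9644282934548875,25.964864595195092,26.922545482547726,26.287454990309527,30.4138126514911,29.832867780352597,29.206163733020468,34.19064199455752,12575.0400390625,12800.0,0.9383662343025208,2786.87890625,0.2216198891401291
5,0.9687720286872251,0.9279349711660819,25.41392585791233,27.387615132099317,26.5323554724288,30.4138126514911,30.479501308256342,30.479501308256342,34.19064199455752,12574.4501953125,12800.0,0.9321261644363403,2805.44775390625,0.2231069952249527
6,0.968721518697725,0.9436725989471508,25.691552233268162,27.22506965014355,26.3735108181384,30.479501308256342,30.4138126514911,29.832867780352597,34.249087579087416,12573.6416015625,12800.0,0.9337681531906128,2800.39453125,0.2227194458246231
7,0.9600487666107627,0.9451159944697117,25.808740875474275,27.307485035162394,26.216517327249516,30.479501308256342,29.832867780352597,29.832867780352597,34.72751070837067,12574.5126953125,12800.0,0.9333599805831909,2801.74853515625,0.22281169891357422
8,0.9931447363090993,0.9570104849050707,25.692402861286993,26.846521816148666,26.662481829915446,30.4138126514911,30.479501308256342,29.832867780352597,34.132096331752024,12575.2060546875,12800.0,0.9387620687484741,2785.728515625,0.22152547538280487
9,0.9817802581234827,0.9401232209796743,25.571480502437332,27.2001371009537,26.70455762396844,30.479501308256342,30.4138126514911,30.479501308256342,34.219877264537345,12573.2451171875,12800.0,0.928068995475769,2817.5322265625,0.22408950328826904
10,0.9809481647677356,0.9370747219445172,25.519750861054597,27.23342148009151,26.714574821242,29.832867780352597,30.4138126514911,30.479501308256342,35.25620512760839,12572.4501953125,12800.0,0.9277323484420776,2818.435546875,0.22417551279067993
11,0.9768301031842109,0.9527940161168831,25.81433048178104,27.09329618482228,26.465547307820334,30.479501308256342,29.832867780352597,29.732137494637012,34.249087579087416,12573.08984375,12800.0,0.9307798147201538,2809.30322265625,0.22343777120113373
12,0.9800485803447215,0.9561288400457107,25.846022268295954,27.031945053618823,26.492619373755648,29.832867780352597,29.832867780352597,30.479501308256342,34.219877264537345,12574.7275390625,12800.0,0.9309126138687134,2809.146484375,0.2233962118625641
13,0.9682588631312042,0.9605773439315725,26.034612865809077,27.10308860632848,26.24280576130791,29.832867780352597,29.832867780352597,30.479501308256342,34.19064199455752,12573.9189453125,12800.0,0.9308269619941711,2809.284423828125,0.22342154383659363
14,0.9751497838204164,0.9673966020595046,26.177069103420916,27.05929403482726,26.386864728394887,30.479501308256342,30.479501308256342,29.832867780352597,34.132096331752024,12572.109375,12800.0,0.9219119548797607,2836.178466796875,0.22559288144111633
15,0.4915212337334737,0.48397351693261265,19.56188541808602,40.419330260192254,19.866959076170424,38.39677720851061,39.15114940841456,22.374650835264447,39.41605003041274,10608.66677970551,10800.0,0.8694958128083268,2685.285716639219,0.25312188349399367
16,0.5337276660729707,0.4820113891570849,18.89225678938001,39.19462737678824,20.91925699241295,38.39677720851061,37.32710141438791,23.358617253596154,38.942264957241505,10609.69850645648,10800.0,0.8846043502608387,2639.593694524033,0.2487906412154616
17,0.5072086001115658,0.48513348369834985,19.304196161195886,39.79151472710757,20.18259848105498,38.39677720851061,38.74677405926847,22.859625981192256,38.862739224094845,10611.069834847412,10800.0,0.8809988235156877,2650.6247237869657,0.2497980660802127
18,0.5081457895915392,0.49478751143100264,19.55427294824114,39.52054669222983,20.08219940401242,38.44801685392889,37.94733192202055,22.374650835264447,39.57982440587629,10611.343015192875,10800.0,0.8828289262009267,2645.175382553991,0.24927809597397238
19,0.5141260518694208,0.47624031931754823,19.015286630279935,39.92792264529138,20.5279852289713,38.74677405926847,38.19113116942204,22.859625981192256,39.437450475404724,10608.82991480351,10800.0,0.8762324115121917,2664.6681772682286,0.25117455918017534
20,0.5087486665556273,0.504302564887877,19.88291014628506,39.426549715656684,20.05820459472949,37.32710141438791,37.32710141438791,22.859625981192256,39.20857686782319,10609.68751293704,10800.0,0.8729163819070843,2674.9348511673647,0.25212192610815853
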