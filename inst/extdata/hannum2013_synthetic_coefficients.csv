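probe_id,coefficient
(Intercept),12.2
cg22736354,-15.9074
cg06493994,-11.5943
cg27578926,-9.0394
cg44130665,14.2196
cg70557007,19.5988
cg20782459,14.037
cg83774985,1.4208
cg73779995,16.5457
cg95067522,0.7515
cg98038889,12.5187
cg20169345,8.0043
cg22238565,12.5147
cg70378801,-3.1473
cg49425261,-1.7792
cg29717162,0.6279
cg05614592,-8.2348
cg63577896,-17.4568
cg13961667,-18.7334
cg97726807,9.1419
cg30834128,-3.2072
cg46718631,1.4206
cg63097583,11.2517
cg03426200,15.2255
cg44634787,2.1149
cg63466055,6.3035
cg34963214,17.4585
cg20056444,-9.5386
cg61064985,1.6925
cg08811547,-19.0585
cg35965047,7.7554
cg51127974,-17.1095
cg50662092,4.9328
cg93381343,-4.9215
cg28609822,5.6184
cg91955452,-3.107
cg62049112,9.9376
cg75786579,13.3168
cg60335901,-17.17
cg07350115,4.4826
cg97496509,18.897
cg26344117,-8.5688
cg37776026,-17.7536
cg98086487,-3.4381
cg62584354,-13.1441
cg64257142,7.2141
cg46345610,14.5638
cg62365914,-8.7942
cg73522215,2.1167
cg31278624,12.0465
cg87633493,7.1758
cg44560704,3.2729
cg82186609,17.6542
cg51880912,15.4738
cg54037881,12.1473
cg81480470,-9.6594
cg92800862,-13.6838
cg82069906,13.4725
cg79935689,10.6632
cg49837442,-15.9915
cg09863515,-6.387
cg57553022,-2.9901
cg44309549,13.6154
cg46488348,-4.1766
cg13994771,10.5265
cg34228204,14.0986
cg45131162,-2.9266
cg93208851,10.5333
cg10185264,-10.7555
cg07448865,18.5388
cg78738534,-3.9447
cg33316282,9.359
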