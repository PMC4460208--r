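formulation_id,d_mm,L_mm,t_min,Q_pct
F1,0.6,14,100,100.8434227658567
F1,0.6,14,200,99.40550044010254
F1,0.6,14,300,101.78507685989246
F1,0.6,14,400,98.66738265279356
F1,0.6,14,500,99.55343147227063
F1,0.6,14,600,100.56960596987805
F1,0.6,14,700,97.11028237072394
F1,0.6,14,800,99.13098165507805
F1,0.6,14,900,99.53829731666461
F1,0.6,14,1000,99.44445908983937
F2,1,10,100,97.16361451149986
F2,1,10,200,99.70352783556015
F2,1,10,300,99.36267463053255
F2,1,10,400,101.32256861638014
F2,1,10,500,98.47859908241263
F2,1,10,600,99.56256798069411
F2,1,10,700,100.97057721864424
F2,1,10,800,100.02822261160618
F2,1,10,900,99.91421780824582
F2,1,10,1000,100.38921440468182
F3,1.5,29,100,85.28851750408425
F3,1.5,29,200,97.54843185509887
F3,1.5,29,300,100.36188452308528
F3,1.5,29,400,100.31319150027097
F3,1.5,29,500,99.74895622776899
F3,1.5,29,600,98.52650920325367
F3,1.5,29,700,99.40361262219591
F3,1.5,29,800,98.85326338901359
F3,1.5,29,900,97.52535770954832
F3,1.5,29,1000,99.38649047875734
F4,2.7,8,100,42.35845712075654
F4,2.7,8,200,71.67724764136373
F4,2.7,8,300,86.62569040624366
F4,2.7,8,400,93.87111338565707
F4,2.7,8,500,95.47274216659164
F4,2.7,8,600,96.54367196467399
F4,2.7,8,700,98.35561770501661
F4,2.7,8,800,100.91543929416866
F4,2.7,8,900,99.94053117602351
F4,2.7,8,1000,100.35845599931714
F5,3.5,5,100,24.776434716687195
F5,3.5,5,200,46.96331871293132
F5,3.5,5,300,66.0884875213168
F5,3.5,5,400,77.09285252696421
F5,3.5,5,500,84.48164732803261
F5,3.5,5,600,90.86615703720797
F5,3.5,5,700,95.16832674558694
F5,3.5,5,800,97.3553178916636
F5,3.5,5,900,98.8716257946366
F5,3.5,5,1000,98.31437151987464
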