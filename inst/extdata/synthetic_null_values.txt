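0.00405225364909327
0.00210292347776290
0.00305837899416967
0.00219011922688736
0.00416573673706404
0.00198764401255815
0.00275673497849155
0.00174823531641660
0.00294803542696137
0.00300941828066940
0.00157195809390119
0.00489921107641522
0.00332277289767173
0.00331026972482074
0.00265194858312179
0.00359620740004643
0.00246637618808058
0.00222674301969993
0.00411866820918696
0.00228750855585382
0.00454961966410718
0.00349283153922634
0.00213277751125744
0.00198075147226510
0.00431666206739886
0.00266318684584705
0.00212195536664808
0.00245124456231388
0.00395577561405127
0.00262950385297768
0.00238889841532942
0.00166551230149992
0.00256618379916722
0.00293803476603366
0.00299349097513420
0.00365198300004539
0.00321128815918681
0.00450290605212812
0.00160973030375814
0.00158499684436101
0.00271231217789837
0.00347959580835580
0.00448671001420789
0.00415462639230639
0.00281116570800356
0.00309429398820530
0.00283952578727135
0.00592706949677815
0.00398543655770559
0.00332692304099296
0.00503190119234146
0.00381955514212468
0.00393400766639438
0.00262279338936059
0.00185201152126943
0.00285385605162521
0.00335719935644218
0.00192603714727558
0.00306555380727121
0.00347495905561298
0.00251780478888235
0.00239459367464038
0.00446322177922575
0.00490157927911991
0.00218592106850341
0.00458546056079440
0.00400631105565555
0.00350193446744294
0.00301381750335793
0.00095658451482680
0.00448520651708401
0.00353301714823390
0.00446598576620567
0.00488646073921016
0.00348965498554003
0.00349880023926048
0.00296056757651995
0.00214056865978900
0.00267224539868558
0.00231485738448751
0.00437454055598720
0.00296760341604858
0.00270519680157417
0.00255078735265507
0.00489790726556193
0.00328487340176010
0.00162946505871959
0.00279502517883791
0.00376072471109599
0.00180275620527001
0.00332319584269032
0.00468090961020810
0.00513710143314552
0.00323468807859611
0.00417570208216057
0.00265655833448301
0.00297914446307133
0.00440160408186060
0.00333371887535355
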