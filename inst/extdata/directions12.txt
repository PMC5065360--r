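 0.03337222762416274  0.15283944372872010  0.98768739936484784
-0.30017256504958173 -0.46321630480118664  0.83386275019207368
 0.38213934082385281 -0.56487935573743076  0.73135547967891534
-0.54683896193566728  0.49772772044334118  0.67322675675540189
 0.44990373642115872  0.62236821704565670  0.64050326335288177
 0.77671420860621232  0.00635758478309857  0.62982110100007838
-0.81879295099172456 -0.15494043356765713  0.55278527969920632
-0.06871422495996445  0.93064272341977050  0.35941963863148041
-0.23189269200790655 -0.92794858365255561  0.29178280533736412
 0.57634808325851850 -0.81062364712749879  0.10349970841477864
 0.81210764488884357  0.58306677335433621  0.02267842417935934
 0.97092220849094146 -0.23938712638618184  0.00196692136063869
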