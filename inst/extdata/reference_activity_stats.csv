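class,tp,fp,tn,fn,tpr,tnr,ppv,npv,acc
stand,2323,54,11998,14,0.994009,0.995519,0.977282,0.998834,0.995274
walk,5309,47,9006,27,0.99494,0.994808,0.991225,0.997011,0.994857
stand_to_sit,119,0,14259,11,0.915385,1,1,0.999229,0.999236
sit,300,26,14045,18,0.943396,0.998152,0.920245,0.99872,0.996942
sit_to_stand,112,1,14268,8,0.933333,0.99993,0.99115,0.99944,0.999375
turn,5414,30,8898,47,0.991394,0.99664,0.994489,0.994746,0.994649
lie_down,1,3,14385,0,1,0.999791,0.25,1,0.999792
bend,577,5,13779,28,0.953719,0.999637,0.991409,0.997972,0.997707
near_fall,58,5,14311,15,0.794521,0.999651,0.920635,0.998953,0.99861
fall,2,0,14387,0,1,1,1,1,1
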