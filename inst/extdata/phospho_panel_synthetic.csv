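sample_id,condition,total_protein,pcJun_like,pMek1_like,pAtf2_like,pp38_like,pJnk_like,pStat1_like,PP01_null,PP02_null
normoxia_1,normoxia,7.70475670965327,63.2474909924065,83.0235456503836,73.4145407100485,62.2052513484964,51.2148128808821,92.4582700282315,62.6624745628835,56.2602717603191
normoxia_2,normoxia,8.41223948784448,58.6038913387252,77.7134064491236,83.5523610710578,50.9297139141962,78.168194586057,71.8566750968108,74.082749884881,59.7479788219965
normoxia_3,normoxia,7.44056775645007,65.0473579910359,82.4725616697484,53.7303701619554,54.6068769399885,46.5726133868781,58.5713614816696,37.1351624162071,38.7015963256304
normoxia_bFGF_1,normoxia_bFGF,10.1657175911585,71.3898360710929,52.1589858094746,81.4549771326545,90.0790369718289,90.6637726785871,73.1514347191258,77.938121651863,76.6444150787261
normoxia_bFGF_2,normoxia_bFGF,10.2641989943265,52.9653072034364,119.065935322695,61.0226162808459,98.2843840928785,87.3102651870734,94.889950602108,134.788115622948,98.5827360463918
normoxia_bFGF_3,normoxia_bFGF,11.1895658300054,92.5357320725346,80.4342615821957,72.3105442494656,106.191344318281,153.173409164697,79.1149899544594,83.6426491752521,79.4988012973063
normoxia_bFGF_4,normoxia_bFGF,10.5852770550963,108.869145595981,95.1079040352555,85.1486323599099,76.7893957442747,120.413897418654,81.5967961402515,90.1369681673011,75.5300756817297
hypoxia_1,hypoxia,11.80629918547,95.1248404681829,128.030570226068,117.526110552486,105.573870036398,89.5092028566639,267.316558371264,97.8015209687094,94.3815700081909
hypoxia_2,hypoxia,13.0868705396643,78.1930755838169,74.2368259064589,79.5142200670164,111.13538012898,98.4148059905357,238.537163657025,168.295631807292,170.912741503843
hypoxia_3,hypoxia,11.6765284716122,121.175720345144,112.533396803594,121.315816580466,98.733759493657,65.2940523205903,153.32098296684,121.911599649927,73.7035017494303
hypoxia_4,hypoxia,12.5855767974611,76.2110123867432,122.329499477907,83.3715265486695,158.155365613025,121.971925786812,216.614651699952,89.4067495743472,89.1499624841768
hypoxia_bFGF_1,hypoxia_bFGF,13.7847892714867,282.558247847082,268.183449794939,204.069991901237,95.3068862668549,72.1296068150846,102.418333754359,101.437953816832,126.257750237036
hypoxia_bFGF_2,hypoxia_bFGF,17.2157688180653,304.767071848838,155.173829731448,324.352242360257,105.918227175201,126.013527121527,252.838109931076,120.519029787286,143.080301381905
hypoxia_bFGF_3,hypoxia_bFGF,12.8889226309579,264.206245068727,184.942338733662,245.513247009041,58.2951786031019,80.7166172008643,148.875063731879,95.7884490826732,74.2741097034862
hypoxia_bFGF_4,hypoxia_bFGF,14.5760804994519,301.107640871031,177.965196133594,186.041192196712,42.6573800029494,112.288472996727,151.354409257021,160.485769047786,159.306323796135
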