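{"sphere":{"center":[0,0,0],"radius_mm":40},"tjd_mm":8,"screws":[{"id":6,"head":[0,-14,44],"neutral_axis":[0,0.0995037190209989,-0.995037190209989],"u_dp":[0,0.995037190209989,0.0995037190209989],"u_ap":[1,-0,0],"radius_mm":1.5},{"id":7,"head":[-3.5,-7,44],"neutral_axis":[-0.0158749750510992,0.0634999002043966,-0.997855574640518],"u_dp":[0.00101009786568967,0.997981844861935,0.0634918658433508],"u_ap":[0.999873474430354,2.16840434497101e-19,-0.0159070780023011],"radius_mm":1.5},{"id":8,"head":[3.5,-7,44],"neutral_axis":[0.0158749750510992,0.0634999002043966,-0.997855574640518],"u_dp":[-0.00101009786568967,0.997981844861935,0.0634918658433508],"u_ap":[0.999873474430354,-2.16840434497101e-19,0.0159070780023011],"radius_mm":1.5},{"id":9,"head":[-3.5,2,44],"neutral_axis":[-0.0431411696486114,-0.00454117575248541,-0.999058665546791],"u_dp":[-0.000195913653645387,0.999989688808232,-0.00453694776863],"u_ap":[0.9990689671385,5.42101086242752e-20,-0.0431416144900716],"radius_mm":1.5},{"id":10,"head":[3.5,2,44],"neutral_axis":[0.0431411696486114,-0.00454117575248541,-0.999058665546791],"u_dp":[0.000195913653645387,0.999989688808232,-0.00453694776863],"u_ap":[0.9990689671385,-5.42101086242752e-20,0.0431416144900716],"radius_mm":1.5},{"id":11,"head":[-3.5,10,44],"neutral_axis":[-0.0158965740005351,-0.0363350262869373,-0.999213222890777],"u_dp":[-0.000577984097361973,0.999339664911149,-0.0363304289770383],"u_ap":[0.999873474430354,1.0842021724855e-19,-0.0159070780023011],"radius_mm":1.5},{"id":12,"head":[3.5,10,44],"neutral_axis":[0.0158965740005351,-0.0363350262869373,-0.999213222890777],"u_dp":[0.000577984097361973,0.999339664911149,-0.0363304289770383],"u_ap":[0.999873474430354,-1.0842021724855e-19,0.0159070780023011],"radius_mm":1.5}]}
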