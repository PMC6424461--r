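G,h,m,p_h
1e6,1,10,9.9999550001199998e-6
1e6,1,100,9.9995050161696079e-5
1e6,1,1000,0.00099950066612559112
1e6,1,5000,0.0049875232948505399
1e6,2,10,8.9999280002939992e-11
1e6,2,100,9.8990298548948914e-9
1e6,2,1000,9.9800357759232256e-7
1e6,2,5000,2.4870438357644651e-5
1e6,3,10,7.1999244003779989e-16
1e6,3,100,9.7005884719248432e-13
1e6,3,1000,9.9551222031422468e-10
1e6,3,5000,1.2399252137470028e-7
1e6,4,10,5.0399395203275990e-21
1e6,4,100,9.4091332854667288e-17
1e6,4,1000,9.9203305681932529e-13
1e6,4,5000,6.1804638967164440e-10
1e6,5,10,3.0239622002015994e-26
1e6,5,100,9.0323569745835760e-21
1e6,5,1000,9.8757549896375299e-16
1e6,5,5000,3.0800670438067515e-12
1e6,6,10,1.5119818560861838e-31
1e6,6,100,8.5803572931663382e-25
1e6,6,1000,9.8215186593471877e-19
1e6,6,5000,1.5346620798004766e-14
1e6,7,10,6.0479364962328477e-37
1e6,7,100,8.0651850137152156e-29
1e6,7,1000,9.7577732780123957e-22
1e6,7,5000,7.6450236519827456e-17
1e6,8,10,1.8143854848302400e-42
1e6,8,100,7.5003032940573950e-33
1e6,8,1000,9.6846983497235461e-25
1e6,8,5000,3.8076617908723515e-19
1e6,9,10,3.6287836704000000e-48
1e6,9,100,6.8999926755519248e-37
1e6,9,1000,9.6025003402054953e-28
1e6,9,5000,1.8960567966817343e-21
1.0725e8,1,10,9.3240089327921593e-8
1.0725e8,1,100,9.3240050206217160e-7
1.0725e8,1,1000,9.3239658990376570e-6
1.0725e8,1,5000,4.6618960139893298e-5
1.0725e8,2,10,7.8243429050451621e-15
1.0725e8,2,100,8.6067699730828904e-13
1.0725e8,2,1000,8.6849404556112202e-11
1.0725e8,2,5000,2.1728927992957344e-9
1.0725e8,3,10,5.8363395600257689e-22
1.0725e8,3,100,7.8644576578118848e-19
1.0725e8,3,1000,8.0816133973059932e-16
1.0725e8,3,5000,1.0125748548572437e-13
1.0725e8,4,10,3.8092658600270848e-29
1.0725e8,4,100,7.1128397394932527e-25
1.0725e8,4,1000,7.5126631763945980e-21
1.0725e8,4,5000,4.7176865004776696e-18
1.0725e8,5,10,2.1310578138563738e-36
1.0725e8,5,100,6.3667349678775175e-31
1.0725e8,5,1000,6.9767626608634430e-26
1.0725e8,5,5000,2.1975770020307877e-22
1.0725e8,6,10,9.9350015095168979e-44
1.0725e8,6,100,5.6395297994335337e-37
1.0725e8,6,1000,6.4725844667402308e-31
1.0725e8,6,5000,1.0234631067865460e-26
1.0725e8,7,10,3.7053619201745334e-51
1.0725e8,7,100,4.9428026679235435e-43
1.0725e8,7,1000,5.9988059261409912e-36
1.0725e8,7,5000,4.7655533102989464e-31
1.0725e8,8,10,1.0364648969361140e-58
1.0725e8,8,100,4.2860649506675822e-49
1.0725e8,8,1000,5.5541136882100110e-41
1.0725e8,8,5000,2.2185412310132702e-35
1.0725e8,9,10,1.9328017356832527e-66
1.0725e8,9,100,3.6766230571704843e-55
1.0725e8,9,1000,5.1372079527157546e-46
1.0725e8,9,5000,1.0326061118324338e-39
8.58e8,1,10,1.1655011593883972e-8
8.58e8,1,100,1.1655010982607162e-7
8.58e8,1,1000,1.1655004869841417e-6
8.58e8,1,5000,5.8274888510226888e-6
8.58e8,2,10,1.2225536587070159e-16
8.58e8,2,100,1.3448088835138425e-14
8.58e8,2,1000,1.3570329953567339e-12
8.58e8,2,5000,3.3952834423103951e-11
8.58e8,3,10,1.1399101679671763e-24
8.58e8,3,100,1.5360287096529144e-21
8.58e8,3,1000,1.5784593753873289e-18
8.58e8,3,5000,1.9778062061665910e-16
8.58e8,4,10,9.2999663890679308e-33
8.58e8,4,100,1.7365358596904520e-28
8.58e8,4,1000,1.8341760915997200e-24
8.58e8,4,5000,1.1518728270024915e-21
8.58e8,5,10,6.5034729955583006e-41
8.58e8,5,100,1.9429770826309730e-35
8.58e8,5,1000,2.1291822053884993e-30
8.58e8,5,5000,6.7071560675760002e-27
8.58e8,6,10,3.7899026802728457e-49
8.58e8,6,100,2.1513148400535105e-42
8.58e8,6,1000,2.4691550971609821e-36
8.58e8,6,5000,3.9046791556207306e-32
8.58e8,7,10,1.7668543994865034e-57
8.58e8,7,100,2.3569182367416718e-49
8.58e8,7,1000,2.8605346793751466e-42
8.58e8,7,5000,2.2727169036035919e-37
8.58e8,8,10,6.1778126036177641e-66
8.58e8,8,100,2.5547014587353619e-56
8.58e8,8,1000,3.3106169069235135e-48
8.58e8,8,5000,1.3225690599798189e-42
8.58e8,9,10,1.4400495638271868e-74
8.58e8,9,100,2.7393067929548934e-63
8.58e8,9,1000,3.8276574479884860e-54
8.58e8,9,5000,7.6949249131645458e-48
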