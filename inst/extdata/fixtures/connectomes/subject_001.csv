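1,0.600120902971697,0.64557729113609,0.556199419052542,0.201271334836421,0.0748765355219264,0.133270453170405,0.121053799733698,0.102342512457994,0.0973143067630845,0.15210857026076,0.223616880765303
0.600120902971697,1,0.57109900144394,0.593422174987973,0.213078438021628,0.105819902671709,0.128932439371873,0.0183327014504392,0.0575347752119451,0.104933125144015,0.0262797751444604,0.144061482445596
0.64557729113609,0.57109900144394,1,0.599595833198729,0.0383618763519081,0.0929540216058215,0.0401292160058356,0.0927462194790342,0.109336615817935,0.0842107030624272,0.099923871017879,0.0609072531972089
0.556199419052542,0.593422174987973,0.599595833198729,1,0.143937031011428,0.147742125812214,0.137556015475307,0.0240505743097179,0.12763860003194,0.151947595464637,0.109812448829645,0.102251474511311
0.201271334836421,0.213078438021628,0.0383618763519081,0.143937031011428,1,0.636328218831835,0.679685098851864,0.590993596484187,0.106071961927516,0.0224287062078296,0.117206833326816,0.0715911729125199
0.0748765355219264,0.105819902671709,0.0929540216058215,0.147742125812214,0.636328218831835,1,0.611859431095849,0.616377214546609,0.173625583506249,0.0966019786988852,0.0817328253338167,0.0863573809471135
0.133270453170405,0.128932439371873,0.0401292160058356,0.137556015475307,0.679685098851864,0.611859431095849,1,0.662591219731895,0.121392961377955,0.0562054045119318,0.117651146571861,0.0670052685629905
0.121053799733698,0.0183327014504392,0.0927462194790342,0.0240505743097179,0.590993596484187,0.616377214546609,0.662591219731895,1,0.11269470030829,0.124866391119416,0.161885552059655,-0.0337568193265609
0.102342512457994,0.0575347752119451,0.109336615817935,0.12763860003194,0.106071961927516,0.173625583506249,0.121392961377955,0.11269470030829,1,0.568620479162395,0.553576557129461,0.523279633447549
0.0973143067630845,0.104933125144015,0.0842107030624272,0.151947595464637,0.0224287062078296,0.0966019786988852,0.0562054045119318,0.124866391119416,0.568620479162395,1,0.540738145816261,0.672735975726963
0.15210857026076,0.0262797751444604,0.099923871017879,0.109812448829645,0.117206833326816,0.0817328253338167,0.117651146571861,0.161885552059655,0.553576557129461,0.540738145816261,1,0.532355160970676
0.223616880765303,0.144061482445596,0.0609072531972089,0.102251474511311,0.0715911729125199,0.0863573809471135,0.0670052685629905,-0.0337568193265609,0.523279633447549,0.672735975726963,0.532355160970676,1
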