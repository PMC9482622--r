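1,0.608079918897592,0.665665395938084,0.626168728577641,0.169466076759511,0.0626211260532435,0.0151000052746943,0.122022111272118,0.0997431312874762,0.114231874537791,0.117058225379533,0.146913999987443
0.608079918897592,1,0.648543523811093,0.599109027945091,0.17485210617854,0.145962302087235,0.0278245123584304,0.131996409403194,0.277133787205886,0.119176159723374,0.0881958551816544,0.103661062828674
0.665665395938084,0.648543523811093,1,0.517606874081535,0.0896954886536234,0.173409824773281,0.173029939380119,0.105191733551828,0.049496563752461,0.105294188699671,0.0715237323717396,0.128778056458474
0.626168728577641,0.599109027945091,0.517606874081535,1,0.0721094373264158,0.0648789860675171,0.112421167614527,-0.0244634894571176,0.176905584538528,0.175707525322067,0.0850242472559626,0.194371655767669
0.169466076759511,0.17485210617854,0.0896954886536234,0.0721094373264158,1,0.63097622912298,0.582203771706637,0.60296987772335,0.0113018384110556,0.0811731069991781,0.132316476043887,0.0828406474399225
0.0626211260532435,0.145962302087235,0.173409824773281,0.0648789860675171,0.63097622912298,1,0.642177446403647,0.758227185948532,0.0526468594372831,0.12616196493329,-0.0433554405304058,0.107216900355939
0.0151000052746943,0.0278245123584304,0.173029939380119,0.112421167614527,0.582203771706637,0.642177446403647,1,0.482051846253509,0.11384222827579,0.110146614167939,0.142185116598871,0.171168661736136
0.122022111272118,0.131996409403194,0.105191733551828,-0.0244634894571176,0.60296987772335,0.758227185948532,0.482051846253509,1,0.0399667118531613,0.0885289671128044,0.13105540842725,0.169061873098299
0.0997431312874762,0.277133787205886,0.049496563752461,0.176905584538528,0.0113018384110556,0.0526468594372831,0.11384222827579,0.0399667118531613,1,0.477797509879904,0.558988127857002,0.523671368375991
0.114231874537791,0.119176159723374,0.105294188699671,0.175707525322067,0.0811731069991781,0.12616196493329,0.110146614167939,0.0885289671128044,0.477797509879904,1,0.545518677548104,0.619158698407403
0.117058225379533,0.0881958551816544,0.0715237323717396,0.0850242472559626,0.132316476043887,-0.0433554405304058,0.142185116598871,0.13105540842725,0.558988127857002,0.545518677548104,1,0.592883455238842
0.146913999987443,0.103661062828674,0.128778056458474,0.194371655767669,0.0828406474399225,0.107216900355939,0.171168661736136,0.169061873098299,0.523671368375991,0.619158698407403,0.592883455238842,1
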