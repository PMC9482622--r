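1,0.678282393102916,0.639137113423901,0.537884551622181,0.111977443959151,0.148834194619802,0.0960421438014613,0.0859441271648875,0.117591460493501,0.0912235037528591,0.197052024462108,0.03956217885077
0.678282393102916,1,0.592018632823613,0.640535468600308,0.156546466564171,0.04804418025276,0.0577409214369221,0.0750989651546968,0.0604323282168612,0.176033522064965,0.117870022417153,0.0891730373476466
0.639137113423901,0.592018632823613,1,0.556084900096221,0.0531839677542843,0.13391620795481,0.0422903684976798,0.147477668107328,0.136745927415769,0.116260297261126,0.0330865222193108,0.0495375214129661
0.537884551622181,0.640535468600308,0.556084900096221,1,0.0978951114260836,0.186460286584125,0.0526637698633467,0.113133175097179,0.0788565234082613,0.0604596795649743,0.0678779018599975,0.0352078031520416
0.111977443959151,0.156546466564171,0.0531839677542843,0.0978951114260836,1,0.602360561641267,0.650516638308246,0.652856214150514,0.0817863664204687,0.146172410542309,0.143696651378229,0.0444130620462808
0.148834194619802,0.04804418025276,0.13391620795481,0.186460286584125,0.602360561641267,1,0.605158512357411,0.592063191658251,0.156007300066769,0.0941012980594666,0.11317896378002,0.153534768943893
0.0960421438014613,0.0577409214369221,0.0422903684976798,0.0526637698633467,0.650516638308246,0.605158512357411,1,0.641158684415425,0.158569908590124,0.0677172769430373,0.160799012309514,0.0905986828538347
0.0859441271648875,0.0750989651546968,0.147477668107328,0.113133175097179,0.652856214150514,0.592063191658251,0.641158684415425,1,0.0894231552166623,0.117624899730313,0.0733507285235416,0.193942854205301
0.117591460493501,0.0604323282168612,0.136745927415769,0.0788565234082613,0.0817863664204687,0.156007300066769,0.158569908590124,0.0894231552166623,1,0.562309199135574,0.653385041050706,0.674377227806976
0.0912235037528591,0.176033522064965,0.116260297261126,0.0604596795649743,0.146172410542309,0.0941012980594666,0.0677172769430373,0.117624899730313,0.562309199135574,1,0.619408775365411,0.57159252722346
0.197052024462108,0.117870022417153,0.0330865222193108,0.0678779018599975,0.143696651378229,0.11317896378002,0.160799012309514,0.0733507285235416,0.653385041050706,0.619408775365411,1,0.616911282595662
0.03956217885077,0.0891730373476466,0.0495375214129661,0.0352078031520416,0.0444130620462808,0.153534768943893,0.0905986828538347,0.193942854205301,0.674377227806976,0.57159252722346,0.616911282595662,1
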