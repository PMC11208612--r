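"sighting_id","group_size","n_distinct","images_distinct","images_total","full_coverage"
"g1",47,12,38,120,TRUE
"g2",18,7,17,67,FALSE
"g3",56,17,45,170,TRUE
"g4",25,5,25,83,TRUE
"g5",15,3,20,53,TRUE
"g6",42,13,38,114,TRUE
"g7",63,15,55,197,TRUE
"g8",20,5,18,50,TRUE
"g9",35,9,44,132,TRUE
"g10",29,7,24,84,TRUE
"g11",4,2,2,10,TRUE
"g12",16,1,11,37,TRUE
"g13",14,3,13,42,TRUE
"g14",18,3,19,54,TRUE
"g15",9,3,13,36,TRUE
"g16",32,11,27,93,TRUE
"g17",47,12,50,165,TRUE
"g18",13,4,11,43,TRUE
"g19",32,10,40,97,TRUE
"g20",1,0,2,6,TRUE
"g21",14,7,20,57,TRUE
"g22",68,29,55,199,TRUE
"g23",34,8,33,117,TRUE
"g24",61,13,51,180,TRUE
"g25",118,37,120,362,TRUE
"g26",13,5,12,47,FALSE
"g27",5,1,6,20,TRUE
"g28",3,1,5,10,TRUE
"g29",29,6,21,80,TRUE
"g30",16,4,14,46,TRUE
"g31",23,12,21,57,TRUE
"g32",58,19,45,183,FALSE
"g33",50,16,37,142,FALSE
"g34",15,2,15,49,TRUE
"g35",25,8,29,87,TRUE
"g36",59,15,37,152,TRUE
"g37",30,8,27,84,TRUE
"g38",31,14,24,83,TRUE
"g39",45,21,30,123,TRUE
"g40",7,3,8,21,TRUE
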