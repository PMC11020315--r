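tooth_id,specimen_id,day_index,width_um,section_plane
rM8,YLSNHM01797,1,9.4121,coronal
rM8,YLSNHM01797,2,12.044,coronal
rM8,YLSNHM01797,3,11.0631,coronal
rM8,YLSNHM01797,4,13.1832,coronal
rM8,YLSNHM01797,5,8.3174,coronal
rM8,YLSNHM01797,6,13.396,coronal
rM8,YLSNHM01797,7,10.5799,coronal
rM8,YLSNHM01797,8,11.6868,coronal
rM8,YLSNHM01797,9,12.4373,coronal
rM8,YLSNHM01797,10,11.3814,coronal
rM8,YLSNHM01797,11,9.7495,coronal
rM8,YLSNHM01797,12,12.4358,coronal
rM8,YLSNHM01797,13,12.2488,coronal
rM8,YLSNHM01797,14,12.4456,coronal
rM8,YLSNHM01797,15,13.1248,coronal
rM8,YLSNHM01797,16,12.1455,coronal
rM8,YLSNHM01797,17,10.1303,coronal
rM8,YLSNHM01797,18,12.9496,coronal
rM8,YLSNHM01797,19,12.2667,coronal
rM8,YLSNHM01797,20,13.2057,coronal
rM8,YLSNHM01797,21,13.254,coronal
rM8,YLSNHM01797,22,12.9004,coronal
rM8,YLSNHM01797,23,10.4828,coronal
rM8,YLSNHM01797,24,10.7041,coronal
rM8,YLSNHM01797,25,11.6035,coronal
rM8,YLSNHM01797,26,10.7959,coronal
rM8,YLSNHM01797,27,11.0278,coronal
rM8,YLSNHM01797,28,11.6684,coronal
rM8,YLSNHM01797,29,13.2169,coronal
rM8,YLSNHM01797,30,14.0298,coronal
rM8,YLSNHM01797,31,12.2101,coronal
rM8,YLSNHM01797,32,12.4537,coronal
rM8,YLSNHM01797,33,10.9989,coronal
rM8,YLSNHM01797,34,10.6942,coronal
rM8,YLSNHM01797,35,12.0187,coronal
rM8,YLSNHM01797,36,10.6368,coronal
rM8,YLSNHM01797,37,12.0963,coronal
rM8,YLSNHM01797,38,10.012,coronal
rM8,YLSNHM01797,39,13.6683,coronal
rM8,YLSNHM01797,40,12.4103,coronal
rM8,YLSNHM01797,41,10.1892,coronal
rM8,YLSNHM01797,42,8.9629,coronal
rM8,YLSNHM01797,43,11.6993,coronal
rM8,YLSNHM01797,44,11.7626,coronal
rM8,YLSNHM01797,45,11.0982,coronal
rM8,YLSNHM01797,46,14.2202,coronal
lPM4,YLSNHM01797,1,14.6083,coronal
lPM4,YLSNHM01797,2,12.1106,coronal
lPM4,YLSNHM01797,3,11.9449,coronal
lPM4,YLSNHM01797,4,12.8576,coronal
lPM4,YLSNHM01797,5,15.1535,coronal
lPM4,YLSNHM01797,6,14.9843,coronal
lPM4,YLSNHM01797,7,14.1112,coronal
lPM4,YLSNHM01797,8,11.7826,coronal
lPM4,YLSNHM01797,9,11.6119,coronal
lPM4,YLSNHM01797,10,15.8055,coronal
lPM4,YLSNHM01797,11,14.1335,coronal
lPM4,YLSNHM01797,12,17.4815,coronal
lPM4,YLSNHM01797,13,13.2809,coronal
lPM4,YLSNHM01797,14,12.5811,coronal
lPM4,YLSNHM01797,15,14.5763,coronal
lPM4,YLSNHM01797,16,14.1532,coronal
lPM4,YLSNHM01797,17,12.6908,coronal
lPM4,YLSNHM01797,18,13.6968,coronal
lPM4,YLSNHM01797,19,12.8926,coronal
lPM4,YLSNHM01797,20,16.4434,coronal
lPM4,YLSNHM01797,21,12.9762,coronal
lPM4,YLSNHM01797,22,10.3882,coronal
lPM4,YLSNHM01797,23,14.6863,coronal
lPM4,YLSNHM01797,24,15.6001,coronal
lPM4,YLSNHM01797,25,13.1755,coronal
lPM4,YLSNHM01797,26,14.492,coronal
lPM4,YLSNHM01797,27,13.1111,coronal
lPM4,YLSNHM01797,28,13.4784,coronal
lPM4,YLSNHM01797,29,17.0756,coronal
lPM4,YLSNHM01797,30,13.6787,coronal
lPM4,YLSNHM01797,31,13.0803,coronal
lPM4,YLSNHM01797,32,11.778,coronal
lPM4,YLSNHM01797,33,13.9495,coronal
rPM5,CUGW VH132,1,11.7175,mesiodistal
rPM5,CUGW VH132,2,13.556,mesiodistal
rPM5,CUGW VH132,3,11.1195,mesiodistal
rPM5,CUGW VH132,4,13.1314,mesiodistal
rPM5,CUGW VH132,5,10.4806,mesiodistal
rPM5,CUGW VH132,6,13.0924,mesiodistal
rPM5,CUGW VH132,7,12.2137,mesiodistal
rPM5,CUGW VH132,8,12.1459,mesiodistal
rPM5,CUGW VH132,9,13.4045,mesiodistal
rPM5,CUGW VH132,10,13.8992,mesiodistal
rPM5,CUGW VH132,11,12.8355,mesiodistal
rPM5,CUGW VH132,12,14.086,mesiodistal
rPM5,CUGW VH132,13,12.9402,mesiodistal
rPM5,CUGW VH132,14,11.4764,mesiodistal
rPM5,CUGW VH132,15,13.6448,mesiodistal
rPM5,CUGW VH132,16,11.5357,mesiodistal
rPM5,CUGW VH132,17,12.3536,mesiodistal
rPM5,CUGW VH132,18,10.7408,mesiodistal
rPM5,CUGW VH132,19,13.7539,mesiodistal
rPM5,CUGW VH132,20,11.1511,mesiodistal
rPM5,CUGW VH132,21,13.7033,mesiodistal
rPM5,CUGW VH132,22,12.0044,mesiodistal
rPM5,CUGW VH132,23,14.9027,mesiodistal
rPM5,CUGW VH132,24,15.6028,mesiodistal
rPM5,CUGW VH132,25,13.0106,mesiodistal
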