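specimen_id,element,side,z_spacing
CUGW VH132,premaxilla,left,2.62
CUGW VH132,premaxilla,right,2.69
CUGW VH132,maxilla,left,2.47
CUGW VH132,maxilla,right,2.49
CUGW VH132,dentary,left,2.58
CUGW VH132,dentary,right,2.48
IVPP V15719,maxilla,left,2.44
IVPP V15719,maxilla,right,2.43
IVPP V15719,dentary,left,2.53
IVPP V15719,dentary,right,2.58
IVPP V12530,maxilla,left,2.52
IVPP V12530,maxilla,right,2.51
IVPP V12530,dentary,left,2.42
IVPP V12530,dentary,right,2.45
IVPP V15718,maxilla,left,2.58
IVPP V15718,maxilla,right,2.53
IVPP V15718,dentary,left,2.60
IVPP V15718,dentary,right,2.62
IVPP V12529,maxilla,left,2.45
IVPP V12529,maxilla,right,2.44
IVPP V12529,dentary,left,2.37
IVPP V12529,dentary,right,2.38
IVPP V15717,premaxilla,left,1.91
IVPP V15717,premaxilla,right,2.13
IVPP V15717,maxilla,left,2.82
IVPP V15717,maxilla,right,2.71
IVPP V15717,dentary,left,2.38
IVPP V15717,dentary,right,2.34
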