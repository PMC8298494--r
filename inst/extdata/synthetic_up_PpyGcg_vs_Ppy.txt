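# synthetic upregulated genes, Ppy+Gcg+ bihormonal vs monohormonal Ppy+ (199 genes, 77 shared with alpha ID)
Gcg
Ttr
Mafb
SynA001
SynA002
SynA003
SynA004
SynA005
SynA006
SynA007
SynA008
SynA009
SynA010
SynA011
SynA012
SynA013
SynA014
SynA015
SynA016
SynA017
SynA018
SynA019
SynA020
SynA021
SynA022
SynA023
SynA024
SynA025
SynA026
SynA027
SynA028
SynA029
SynA030
SynA031
SynA032
SynA033
SynA034
SynA035
SynA036
SynA037
SynA038
SynA039
SynA040
SynA041
SynA042
SynA043
SynA044
SynA045
SynA046
SynA047
SynA048
SynA049
SynA050
SynA051
SynA052
SynA053
SynA054
SynA055
SynA056
SynA057
SynA058
SynA059
SynA060
SynA061
SynA062
SynA063
SynA064
SynA065
SynA066
SynA067
SynA068
SynA069
SynA070
SynA071
SynA072
SynA073
SynA074
Iapp
Chga
SynUA001
SynUA002
SynUA003
SynUA004
SynUA005
SynUA006
SynUA007
SynUA008
SynUA009
SynUA010
SynUA011
SynUA012
SynUA013
SynUA014
SynUA015
SynUA016
SynUA017
SynUA018
SynUA019
SynUA020
SynUA021
SynUA022
SynUA023
SynUA024
SynUA025
SynUA026
SynUA027
SynUA028
SynUA029
SynUA030
SynUA031
SynUA032
SynUA033
SynUA034
SynUA035
SynUA036
SynUA037
SynUA038
SynUA039
SynUA040
SynUA041
SynUA042
SynUA043
SynUA044
SynUA045
SynUA046
SynUA047
SynUA048
SynUA049
SynUA050
SynUA051
SynUA052
SynUA053
SynUA054
SynUA055
SynUA056
SynUA057
SynUA058
SynUA059
SynUA060
SynUA061
SynUA062
SynUA063
SynUA064
SynUA065
SynUA066
SynUA067
SynUA068
SynUA069
SynUA070
SynUA071
SynUA072
SynUA073
SynUA074
SynUA075
SynUA076
SynUA077
SynUA078
SynUA079
SynUA080
SynUA081
SynUA082
SynUA083
SynUA084
SynUA085
SynUA086
SynUA087
SynUA088
SynUA089
SynUA090
SynUA091
SynUA092
SynUA093
SynUA094
SynUA095
SynUA096
SynUA097
SynUA098
SynUA099
SynUA100
SynUA101
SynUA102
SynUA103
SynUA104
SynUA105
SynUA106
SynUA107
SynUA108
SynUA109
SynUA110
SynUA111
SynUA112
SynUA113
SynUA114
SynUA115
SynUA116
SynUA117
SynUA118
SynUA119
SynUA120
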