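# synthetic mouse alpha-cell ID gene list (82 genes; placeholder names except printed markers)
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
SynA075
SynA076
SynA077
SynA078
SynA079
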