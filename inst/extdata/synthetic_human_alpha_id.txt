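# synthetic human alpha-cell ID gene list (99 genes)
GCG
TTR
MAFB
SYNHA001
SYNHA002
SYNHA003
SYNHA004
SYNHA005
SYNHA006
SYNHA007
SYNHA008
SYNHA009
SYNHA010
SYNHA011
SYNHA012
SYNHA013
SYNHA014
SYNHA015
SYNHA016
SYNHA017
SYNHA018
SYNHA019
SYNHA020
SYNHA021
SYNHA022
SYNHA023
SYNHA024
SYNHA025
SYNHA026
SYNHA027
SYNHA028
SYNHA029
SYNHA030
SYNHA031
SYNHA032
SYNHA033
SYNHA034
SYNHA035
SYNHA036
SYNHA037
SYNHA038
SYNHA039
SYNHA040
SYNHA041
SYNHA042
SYNHA043
SYNHA044
SYNHA045
SYNHA046
SYNHA047
SYNHA048
SYNHA049
SYNHA050
SYNHA051
SYNHA052
SYNHA053
SYNHA054
SYNHA055
SYNHA056
SYNHA057
SYNHA058
SYNHA059
SYNHA060
SYNHA061
SYNHA062
SYNHA063
SYNHA064
SYNHA065
SYNHA066
SYNHA067
SYNHA068
SYNHA069
SYNHA070
SYNHA071
SYNHA072
SYNHA073
SYNHA074
SYNHA075
SYNHA076
SYNHA077
SYNHA078
SYNHA079
SYNHA080
SYNHA081
SYNHA082
SYNHA083
SYNHA084
SYNHA085
SYNHA086
SYNHA087
SYNHA088
SYNHA089
SYNHA090
SYNHA091
SYNHA092
SYNHA093
SYNHA094
SYNHA095
SYNHA096
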