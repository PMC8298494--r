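# synthetic upregulated genes, Ppy+Sst+ bihormonal vs monohormonal Ppy+ (120 genes, 6 shared with delta ID)
Sst
Hhex
SynD001
SynD002
SynD003
SynD004
Iapp
Chga
SynUD001
SynUD002
SynUD003
SynUD004
SynUD005
SynUD006
SynUD007
SynUD008
SynUD009
SynUD010
SynUD011
SynUD012
SynUD013
SynUD014
SynUD015
SynUD016
SynUD017
SynUD018
SynUD019
SynUD020
SynUD021
SynUD022
SynUD023
SynUD024
SynUD025
SynUD026
SynUD027
SynUD028
SynUD029
SynUD030
SynUD031
SynUD032
SynUD033
SynUD034
SynUD035
SynUD036
SynUD037
SynUD038
SynUD039
SynUD040
SynUD041
SynUD042
SynUD043
SynUD044
SynUD045
SynUD046
SynUD047
SynUD048
SynUD049
SynUD050
SynUD051
SynUD052
SynUD053
SynUD054
SynUD055
SynUD056
SynUD057
SynUD058
SynUD059
SynUD060
SynUD061
SynUD062
SynUD063
SynUD064
SynUD065
SynUD066
SynUD067
SynUD068
SynUD069
SynUD070
SynUD071
SynUD072
SynUD073
SynUD074
SynUD075
SynUD076
SynUD077
SynUD078
SynUD079
SynUD080
SynUD081
SynUD082
SynUD083
SynUD084
SynUD085
SynUD086
SynUD087
SynUD088
SynUD089
SynUD090
SynUD091
SynUD092
SynUD093
SynUD094
SynUD095
SynUD096
SynUD097
SynUD098
SynUD099
SynUD100
SynUD101
SynUD102
SynUD103
SynUD104
SynUD105
SynUD106
SynUD107
SynUD108
SynUD109
SynUD110
SynUD111
SynUD112
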