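# synthetic mouse beta-cell ID gene list (134 genes)
Ins1
Ins2
Nkx6-1
SynB001
SynB002
SynB003
SynB004
SynB005
SynB006
SynB007
SynB008
SynB009
SynB010
SynB011
SynB012
SynB013
SynB014
SynB015
SynB016
SynB017
SynB018
SynB019
SynB020
SynB021
SynB022
SynB023
SynB024
SynB025
SynB026
SynB027
SynB028
SynB029
SynB030
SynB031
SynB032
SynB033
SynB034
SynB035
SynB036
SynB037
SynB038
SynB039
SynB040
SynB041
SynB042
SynB043
SynB044
SynB045
SynB046
SynB047
SynB048
SynB049
SynB050
SynB051
SynB052
SynB053
SynB054
SynB055
SynB056
SynB057
SynB058
SynB059
SynB060
SynB061
SynB062
SynB063
SynB064
SynB065
SynB066
SynB067
SynB068
SynB069
SynB070
SynB071
SynB072
SynB073
SynB074
SynB075
SynB076
SynB077
SynB078
SynB079
SynB080
SynB081
SynB082
SynB083
SynB084
SynB085
SynB086
SynB087
SynB088
SynB089
SynB090
SynB091
SynB092
SynB093
SynB094
SynB095
SynB096
SynB097
SynB098
SynB099
SynB100
SynB101
SynB102
SynB103
SynB104
SynB105
SynB106
SynB107
SynB108
SynB109
SynB110
SynB111
SynB112
SynB113
SynB114
SynB115
SynB116
SynB117
SynB118
SynB119
SynB120
SynB121
SynB122
SynB123
SynB124
SynB125
SynB126
SynB127
SynB128
SynB129
SynB130
SynB131
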