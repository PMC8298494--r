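# synthetic upregulated genes, Ppy+Ins2+ bihormonal vs monohormonal Ppy+ (150 genes, 35 shared with beta ID)
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
Iapp
Chga
SynUB001
SynUB002
SynUB003
SynUB004
SynUB005
SynUB006
SynUB007
SynUB008
SynUB009
SynUB010
SynUB011
SynUB012
SynUB013
SynUB014
SynUB015
SynUB016
SynUB017
SynUB018
SynUB019
SynUB020
SynUB021
SynUB022
SynUB023
SynUB024
SynUB025
SynUB026
SynUB027
SynUB028
SynUB029
SynUB030
SynUB031
SynUB032
SynUB033
SynUB034
SynUB035
SynUB036
SynUB037
SynUB038
SynUB039
SynUB040
SynUB041
SynUB042
SynUB043
SynUB044
SynUB045
SynUB046
SynUB047
SynUB048
SynUB049
SynUB050
SynUB051
SynUB052
SynUB053
SynUB054
SynUB055
SynUB056
SynUB057
SynUB058
SynUB059
SynUB060
SynUB061
SynUB062
SynUB063
SynUB064
SynUB065
SynUB066
SynUB067
SynUB068
SynUB069
SynUB070
SynUB071
SynUB072
SynUB073
SynUB074
SynUB075
SynUB076
SynUB077
SynUB078
SynUB079
SynUB080
SynUB081
SynUB082
SynUB083
SynUB084
SynUB085
SynUB086
SynUB087
SynUB088
SynUB089
SynUB090
SynUB091
SynUB092
SynUB093
SynUB094
SynUB095
SynUB096
SynUB097
SynUB098
SynUB099
SynUB100
SynUB101
SynUB102
SynUB103
SynUB104
SynUB105
SynUB106
SynUB107
SynUB108
SynUB109
SynUB110
SynUB111
SynUB112
SynUB113
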