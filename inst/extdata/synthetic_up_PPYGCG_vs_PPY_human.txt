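# synthetic upregulated genes, human PPY+GCG+ vs PPY+ (70 genes, 26 shared with human alpha ID)
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
CHGA
SYNHU001
SYNHU002
SYNHU003
SYNHU004
SYNHU005
SYNHU006
SYNHU007
SYNHU008
SYNHU009
SYNHU010
SYNHU011
SYNHU012
SYNHU013
SYNHU014
SYNHU015
SYNHU016
SYNHU017
SYNHU018
SYNHU019
SYNHU020
SYNHU021
SYNHU022
SYNHU023
SYNHU024
SYNHU025
SYNHU026
SYNHU027
SYNHU028
SYNHU029
SYNHU030
SYNHU031
SYNHU032
SYNHU033
SYNHU034
SYNHU035
SYNHU036
SYNHU037
SYNHU038
SYNHU039
SYNHU040
SYNHU041
SYNHU042
SYNHU043
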