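species,group
Campanulaceae_sp1,Campanulaceae
Family028_sp1,Family028
Asteraceae_sp1,Asteraceae
Rubiaceae_sp1,Rubiaceae
Lamiaceae_sp1,Lamiaceae
Heliconiaceae_sp1,Heliconiaceae
Family048_sp1,Family048
Family044_sp1,Family044
Rutaceae_x1,Rutaceae
Ericaceae_sp1,Ericaceae
Family019_sp1,Family019
Family005_sp1,Family005
Fabaceae_sp1,Fabaceae
Family029_sp1,Family029
Family042_sp1,Family042
Family020_sp1,Family020
Loranthaceae_sp1,Loranthaceae
Strelitziaceae_x1,Strelitziaceae
Malvaceae_sp1,Malvaceae
Family052_sp1,Family052
Gesneriaceae_sp1,Gesneriaceae
Family027_sp1,Family027
Family022_sp1,Family022
Family032_sp1,Family032
Family003_sp1,Family003
Marcgraviaceae_sp1,Marcgraviaceae
Bromeliaceae_sp1,Bromeliaceae
Family001_sp1,Family001
Family045_sp1,Family045
Family072_sp1,Family072
Family004_sp1,Family004
Musaceae_x1,Musaceae
Solanaceae_sp1,Solanaceae
Family002_sp1,Family002
Family037_sp1,Family037
Family015_sp1,Family015
Family060_sp1,Family060
Family035_sp1,Family035
Family046_sp1,Family046
Family008_sp1,Family008
Family034_sp1,Family034
Strelitziaceae_sp1,Strelitziaceae
Family011_sp1,Family011
Family038_sp1,Family038
Family021_sp1,Family021
Family013_sp1,Family013
Family030_sp1,Family030
Family056_sp1,Family056
Family080_sp1,Family080
Family016_sp1,Family016
Family009_sp1,Family009
Family040_sp1,Family040
Myrtaceae_x1,Myrtaceae
Family047_sp1,Family047
Family026_sp1,Family026
Fabaceae_sp2,Fabaceae
Family024_sp1,Family024
Family007_sp1,Family007
Family049_sp1,Family049
Family033_sp1,Family033
Family051_sp1,Family051
Family055_sp1,Family055
Family074_sp1,Family074
Family062_sp1,Family062
Family012_sp1,Family012
Family054_sp1,Family054
Family058_sp1,Family058
Family006_sp1,Family006
Family064_sp1,Family064
Vitaceae_x1,Vitaceae
Family014_sp1,Family014
Family069_sp1,Family069
Family023_sp1,Family023
Family050_sp1,Family050
Family036_sp1,Family036
Fabaceae_x9,Fabaceae
Family084_sp1,Family084
Family031_sp1,Family031
Family010_sp1,Family010
Family053_sp1,Family053
Family025_sp1,Family025
Family070_sp1,Family070
Family018_sp1,Family018
Xanthorrhoeaceae_x1,Xanthorrhoeaceae
Family039_sp1,Family039
Family017_sp1,Family017
Oleaceae_x1,Oleaceae
Family057_sp1,Family057
Family065_sp1,Family065
Family075_sp1,Family075
Pittosporaceae_x1,Pittosporaceae
Family043_sp1,Family043
Family073_sp1,Family073
Family061_sp1,Family061
Family071_sp1,Family071
Family082_sp1,Family082
Family041_sp1,Family041
Family063_sp1,Family063
Family076_sp1,Family076
Family079_sp1,Family079
Family081_sp1,Family081
Rutaceae_sp1,Rutaceae
Family068_sp1,Family068
Myrtaceae_sp1,Myrtaceae
Family077_sp1,Family077
Family059_sp1,Family059
Family083_sp1,Family083
Family066_sp1,Family066
Family067_sp1,Family067
Family078_sp1,Family078
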