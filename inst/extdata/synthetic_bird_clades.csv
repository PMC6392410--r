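species,group
Emeralds_bird1,Emeralds
Emeralds_bird2,Emeralds
Emeralds_bird3,Emeralds
Bees_bird1,Bees
Bees_bird2,Bees
Bees_bird3,Bees
MountainGems_bird1,Mountain Gems
MountainGems_bird2,Mountain Gems
MountainGems_bird3,Mountain Gems
Hermits_bird1,Hermits
Hermits_bird2,Hermits
Hermits_bird3,Hermits
Coquettes_bird1,Coquettes
Coquettes_bird2,Coquettes
Coquettes_bird3,Coquettes
Mangoes_bird1,Mangoes
Mangoes_bird2,Mangoes
Mangoes_bird3,Mangoes
Brilliants_bird1,Brilliants
Brilliants_bird2,Brilliants
Brilliants_bird3,Brilliants
Topazes_bird1,Topazes
Topazes_bird2,Topazes
Topazes_bird3,Topazes
Patagona_bird1,Patagona
Patagona_bird2,Patagona
Patagona_bird3,Patagona
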