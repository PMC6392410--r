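family,Emeralds,Bees,Mountain Gems,Hermits,Coquettes,Mangoes,Brilliants,Topazes,Patagona
Asteraceae,1,1,1,1,1,1,1,1,1
Bromeliaceae,1,1,1,1,1,1,1,1,1
Campanulaceae,1,1,1,1,1,1,1,1,1
Ericaceae,1,1,1,1,1,1,1,1,1
Fabaceae,1,1,1,1,1,1,1,1,1
Gesneriaceae,1,1,1,1,1,1,1,1,1
Heliconiaceae,1,1,1,1,1,1,1,1,1
Lamiaceae,1,1,1,1,1,1,1,1,1
Loranthaceae,1,1,1,1,1,1,1,1,1
Malvaceae,1,1,1,1,1,1,1,1,1
Marcgraviaceae,1,1,1,1,1,1,1,1,1
Rubiaceae,1,1,1,1,1,1,1,1,1
Solanaceae,1,1,1,1,1,1,1,1,1
Family001,1,1,1,1,1,1,1,1,0
Family002,1,1,1,1,1,1,1,1,0
Family003,1,1,1,1,1,1,1,1,0
Family004,1,1,1,1,1,1,1,1,0
Myrtaceae,1,1,1,1,1,1,1,1,0
Family005,1,1,1,1,1,1,1,0,0
Family006,1,1,1,1,1,1,1,0,0
Family007,1,1,1,1,1,1,1,0,0
Family008,1,1,1,1,1,1,1,0,0
Family009,1,1,1,1,1,1,0,0,0
Family010,1,1,1,1,1,1,0,0,0
Family011,1,1,1,1,1,1,0,0,0
Family012,1,1,1,1,1,1,0,0,0
Family013,1,1,1,1,1,1,0,0,0
Strelitziaceae,1,1,1,1,1,1,0,0,0
Family014,1,1,1,1,1,0,0,0,0
Family015,1,1,1,1,1,0,0,0,0
Family016,1,1,1,1,1,0,0,0,0
Family017,1,1,1,1,1,0,0,0,0
Family018,1,1,1,1,1,0,0,0,0
Family019,1,1,1,1,1,0,0,0,0
Rutaceae,1,1,1,1,1,0,0,0,0
Family020,1,1,1,1,0,0,0,0,0
Family021,1,1,1,1,0,0,0,0,0
Family022,1,1,1,1,0,0,0,0,0
Family023,1,1,1,1,0,0,0,0,0
Family024,1,1,1,1,0,0,0,0,0
Family025,1,1,1,1,0,0,0,0,0
Family026,1,1,1,1,0,0,0,0,0
Family027,1,1,1,1,0,0,0,0,0
Family028,1,1,1,1,0,0,0,0,0
Family029,1,1,1,1,0,0,0,0,0
Musaceae,1,1,1,1,0,0,0,0,0
Family030,1,1,1,0,0,0,0,0,0
Family031,1,1,1,0,0,0,0,0,0
Family032,1,1,1,0,0,0,0,0,0
Family033,1,1,1,0,0,0,0,0,0
Family034,1,1,1,0,0,0,0,0,0
Family035,1,1,1,0,0,0,0,0,0
Family036,1,1,1,0,0,0,0,0,0
Family037,1,1,1,0,0,0,0,0,0
Family038,1,1,1,0,0,0,0,0,0
Family039,1,1,1,0,0,0,0,0,0
Family040,1,1,1,0,0,0,0,0,0
Family041,1,1,1,0,0,0,0,0,0
Family042,1,1,1,0,0,0,0,0,0
Family043,1,1,1,0,0,0,0,0,0
Family044,1,1,0,0,0,0,0,0,0
Family045,1,1,0,0,0,0,0,0,0
Family046,1,1,0,0,0,0,0,0,0
Family047,1,1,0,0,0,0,0,0,0
Family048,1,1,0,0,0,0,0,0,0
Family049,1,1,0,0,0,0,0,0,0
Family050,1,1,0,0,0,0,0,0,0
Family051,1,1,0,0,0,0,0,0,0
Family052,1,1,0,0,0,0,0,0,0
Family053,1,1,0,0,0,0,0,0,0
Family054,1,1,0,0,0,0,0,0,0
Family055,1,1,0,0,0,0,0,0,0
Family056,1,1,0,0,0,0,0,0,0
Family057,1,1,0,0,0,0,0,0,0
Family058,1,1,0,0,0,0,0,0,0
Family059,1,1,0,0,0,0,0,0,0
Family060,1,1,0,0,0,0,0,0,0
Family061,1,1,0,0,0,0,0,0,0
Family062,1,1,0,0,0,0,0,0,0
Family063,1,1,0,0,0,0,0,0,0
Oleaceae,1,1,0,0,0,0,0,0,0
Vitaceae,1,1,0,0,0,0,0,0,0
Family064,1,0,0,0,0,0,0,0,0
Family065,1,0,0,0,0,0,0,0,0
Family066,1,0,0,0,0,0,0,0,0
Family067,1,0,0,0,0,0,0,0,0
Family068,1,0,0,0,0,0,0,0,0
Family069,1,0,0,0,0,0,0,0,0
Family070,1,0,0,0,0,0,0,0,0
Family071,1,0,0,0,0,0,0,0,0
Family072,1,0,0,0,0,0,0,0,0
Family073,1,0,0,0,0,0,0,0,0
Family074,1,0,0,0,0,0,0,0,0
Family075,1,0,0,0,0,0,0,0,0
Family076,1,0,0,0,0,0,0,0,0
Family077,1,0,0,0,0,0,0,0,0
Family078,1,0,0,0,0,0,0,0,0
Family079,1,0,0,0,0,0,0,0,0
Family080,1,0,0,0,0,0,0,0,0
Family081,1,0,0,0,0,0,0,0,0
Family082,1,0,0,0,0,0,0,0,0
Family083,1,0,0,0,0,0,0,0,0
Family084,1,0,0,0,0,0,0,0,0
Pittosporaceae,1,0,0,0,0,0,0,0,0
Xanthorrhoeaceae,1,0,0,0,0,0,0,0,0
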