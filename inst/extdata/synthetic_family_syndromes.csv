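family,syndrome
Campanulaceae,ornithophilous
Family028,intermediate
Asteraceae,ornithophilous
Rubiaceae,ornithophilous
Lamiaceae,ornithophilous
Heliconiaceae,ornithophilous
Family048,non-ornithophilous
Family044,non-ornithophilous
Rutaceae,non-ornithophilous
Ericaceae,ornithophilous
Family019,intermediate
Family005,intermediate
Fabaceae,ornithophilous
Family029,intermediate
Family042,non-ornithophilous
Family020,intermediate
Loranthaceae,ornithophilous
Strelitziaceae,non-ornithophilous
Malvaceae,ornithophilous
Family052,non-ornithophilous
Gesneriaceae,ornithophilous
Family027,intermediate
Family022,intermediate
Family032,intermediate
Family003,intermediate
Marcgraviaceae,ornithophilous
Bromeliaceae,ornithophilous
Family001,ornithophilous
Family045,non-ornithophilous
Family072,non-ornithophilous
Family004,intermediate
Musaceae,non-ornithophilous
Solanaceae,ornithophilous
Family002,intermediate
Family037,intermediate
Family015,intermediate
Family060,non-ornithophilous
Family035,intermediate
Family046,non-ornithophilous
Family008,intermediate
Family034,intermediate
Family011,intermediate
Family038,non-ornithophilous
Family021,intermediate
Family013,intermediate
Family030,intermediate
Family056,non-ornithophilous
Family080,non-ornithophilous
Family016,intermediate
Family009,intermediate
Family040,non-ornithophilous
Myrtaceae,non-ornithophilous
Family047,non-ornithophilous
Family026,intermediate
Family024,intermediate
Family007,intermediate
Family049,non-ornithophilous
Family033,intermediate
Family051,non-ornithophilous
Family055,non-ornithophilous
Family074,non-ornithophilous
Family062,non-ornithophilous
Family012,intermediate
Family054,non-ornithophilous
Family058,non-ornithophilous
Family006,intermediate
Family064,non-ornithophilous
Vitaceae,non-ornithophilous
Family014,intermediate
Family069,non-ornithophilous
Family023,intermediate
Family050,non-ornithophilous
Family036,intermediate
Family084,non-ornithophilous
Family031,intermediate
Family010,intermediate
Family053,non-ornithophilous
Family025,intermediate
Family070,non-ornithophilous
Family018,intermediate
Xanthorrhoeaceae,non-ornithophilous
Family039,non-ornithophilous
Family017,intermediate
Oleaceae,non-ornithophilous
Family057,non-ornithophilous
Family065,non-ornithophilous
Family075,non-ornithophilous
Pittosporaceae,non-ornithophilous
Family043,non-ornithophilous
Family073,non-ornithophilous
Family061,non-ornithophilous
Family071,non-ornithophilous
Family082,non-ornithophilous
Family041,non-ornithophilous
Family063,non-ornithophilous
Family076,non-ornithophilous
Family079,non-ornithophilous
Family081,non-ornithophilous
Family068,non-ornithophilous
Family077,non-ornithophilous
Family059,non-ornithophilous
Family083,non-ornithophilous
Family066,non-ornithophilous
Family067,non-ornithophilous
Family078,non-ornithophilous
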