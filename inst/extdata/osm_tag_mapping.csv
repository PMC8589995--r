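tag,category
landuse=residential,land_use_residential
landuse=commercial,land_use_commercial
landuse=industrial,land_use_industrial
landuse=retail,land_use_retail
landuse=natural,land_use_natural
landuse=forest,land_use_natural
landuse=meadow,land_use_natural
landuse=grass,land_use_natural
natural=wood,land_use_natural
natural=water,land_use_natural
highway=residential,roads_residential
highway=living_street,roads_residential
highway=motorway,roads_main
highway=trunk,roads_main
highway=primary,roads_main
highway=secondary,roads_main
highway=tertiary,roads_other
highway=unclassified,roads_other
highway=service,roads_other
highway=track,roads_other
highway=cycleway,roads_other
highway=footway,roads_other
railway=station,transport
amenity=bus_station,transport
highway=bus_stop,transport
amenity=parking,transport
amenity=ferry_terminal,transport
aeroway=aerodrome,transport
amenity=bar,food
amenity=cafe,food
amenity=restaurant,food
amenity=pub,food
amenity=fast_food,food
amenity=food_court,food
amenity=clinic,health
amenity=hospital,health
amenity=pharmacy,health
amenity=doctors,health
amenity=dentist,health
amenity=veterinary,health
amenity=school,education
amenity=college,education
amenity=kindergarten,education
amenity=university,education
amenity=library,education
shop=supermarket,retail
shop=department_store,retail
shop=mall,retail
shop=convenience,retail
shop=bakery,retail
shop=clothes,retail
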