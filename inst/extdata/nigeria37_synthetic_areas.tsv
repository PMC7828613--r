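area	region
Benue	North-Central
FCT	North-Central
Kogi	North-Central
Kwara	North-Central
Nasarawa	North-Central
Niger	North-Central
Plateau	North-Central
Adamawa	North-East
Bauchi	North-East
Borno	North-East
Gombe	North-East
Taraba	North-East
Yobe	North-East
Jigawa	North-West
Kaduna	North-West
Kano	North-West
Katsina	North-West
Kebbi	North-West
Sokoto	North-West
Zamfara	North-West
Abia	South-East
Anambra	South-East
Ebonyi	South-East
Enugu	South-East
Imo	South-East
AkwaIbom	South-South
Bayelsa	South-South
CrossRiver	South-South
Delta	South-South
Edo	South-South
Rivers	South-South
Ekiti	South-West
Lagos	South-West
Ogun	South-West
Ondo	South-West
Osun	South-West
Oyo	South-West
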