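Sokoto Zamfara
Sokoto Kebbi
Zamfara Kebbi
Zamfara Katsina
Zamfara Kaduna
Zamfara Niger
Kebbi Niger
Katsina Kaduna
Katsina Kano
Katsina Jigawa
Kano Jigawa
Kano Kaduna
Kano Bauchi
Jigawa Bauchi
Jigawa Yobe
Yobe Borno
Yobe Gombe
Yobe Bauchi
Borno Gombe
Borno Adamawa
Gombe Adamawa
Gombe Bauchi
Gombe Taraba
Adamawa Taraba
Taraba Bauchi
Taraba Plateau
Taraba Nasarawa
Taraba Benue
Bauchi Plateau
Bauchi Kaduna
Kaduna Plateau
Kaduna Nasarawa
Kaduna Niger
Kaduna FCT
Plateau Nasarawa
Nasarawa Benue
Nasarawa Kogi
Nasarawa FCT
FCT Kogi
FCT Niger
Niger Kogi
Niger Kwara
Kwara Kogi
Kwara Oyo
Kwara Osun
Kwara Ekiti
Kogi Benue
Kogi Enugu
Kogi Anambra
Kogi Edo
Kogi Ondo
Kogi Ekiti
Benue Enugu
Benue Ebonyi
Benue CrossRiver
Oyo Ogun
Oyo Osun
Osun Ekiti
Osun Ondo
Osun Ogun
Ekiti Ondo
Ondo Ogun
Ondo Edo
Ondo Delta
Ogun Lagos
Edo Delta
Edo Anambra
Delta Anambra
Delta Imo
Delta Bayelsa
Delta Rivers
Anambra Enugu
Anambra Imo
Anambra Abia
Enugu Ebonyi
Enugu Abia
Ebonyi Abia
Ebonyi CrossRiver
Abia Imo
Abia Rivers
Abia AkwaIbom
Abia CrossRiver
Imo Rivers
Rivers Bayelsa
Rivers AkwaIbom
AkwaIbom CrossRiver
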