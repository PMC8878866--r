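"file","md5"
"ALDO.rxn","ac4efe6c55a8ae93612a72b0a80a0f79"
"compounds.csv","d762311de9d507c743e02cee3c615e7a"
"ENO.rxn","18a1201133ff889a269fffee7ee84034"
"FH.rxn","c5edbb65ed998aecc62ad68c0eb6f27b"
"GAD.rxn","16fef034e3384a078427a4e1ba09c509"
"GAPDH.rxn","7d6b474cd87f8dab249e7b6d738aa3c8"
"GLS.rxn","9c282152ce74e2ee8d7c430e4b4aa931"
"GLUD.rxn","35dcd02248eaf234435184ddb3c4e3e9"
"glutamine_model.csv","5b214923934c3480c87d5ec0e2e59f5a"
"glycolysis_model.csv","798bf66437bbcc17a0daa07a27ccf345"
"HK_ATP.rxn","0784a50a94b93c91a9a0b3539cded1ac"
"HK.rxn","7d9e48b7f095acc782be507aaac50314"
"index.csv","a2f95a833ac973d523bf90e3b5113b17"
"PDH.rxn","0bad7bdb9e0136787e4b92fb9eb03a1a"
"PFK.rxn","4b850bc0f60b0e45f4ace497eba9f913"
"PGI.rxn","eb7adc4113a3a92b34462d29b09604df"
"PGK.rxn","211a60d7425d308b002c6e661976ce6d"
"PGM.rxn","c64804dd476d886e50cc77b5aeacb928"
"PK.rxn","9ca32547f8750c56a68ada9d8b843e56"
"TPI.rxn","e09344af2c99cdaa9d13d383bf477084"
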