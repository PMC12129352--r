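1,-0.074012942782063273,-0.096200580377391764,-0.049342658489273217,-0.058526279023894401,0.1079214017868575,0.10572202940283781,-0.09347932236683798,0.023280406847521196,-0.11793088351191305
-0.074012942782063273,1,-0.02647270450952692,-0.034031841142335179,0.02524792883612597,0.13384626063478977,0.029168392823793854,-0.10707889780307533,0.17158822477195002,0.020999626316178844
-0.096200580377391764,-0.02647270450952692,1,0.09696316706633859,0.026257537891756749,-0.13515600168073735,0.12697662364011658,-0.14876078801624079,0.013621967674500919,3.4166064534470186e-05
-0.049342658489273217,-0.034031841142335179,0.09696316706633859,1,0.19029263994481976,0.052297178323217591,0.10096612447115633,0.003160390664279436,0.137715322214848,0.005159703234180372
-0.058526279023894401,0.02524792883612597,0.026257537891756749,0.19029263994481976,1,0.13775457007553285,0.017930803893094663,-0.13949583840844923,0.13016191382475711,0.0049694826919710628
0.1079214017868575,0.13384626063478977,-0.13515600168073735,0.052297178323217591,0.13775457007553285,1,-0.030180973594008252,-0.070115088153015898,-0.079119563145328753,-0.0804668175203056
0.10572202940283781,0.029168392823793854,0.12697662364011658,0.10096612447115633,0.017930803893094663,-0.030180973594008252,1,-0.12767177782263733,-0.013695358096756382,-0.10265251385203836
-0.09347932236683798,-0.10707889780307533,-0.14876078801624079,0.003160390664279436,-0.13949583840844923,-0.070115088153015898,-0.12767177782263733,1,-0.059222174457035683,0.061019288547388258
0.023280406847521196,0.17158822477195002,0.013621967674500919,0.137715322214848,0.13016191382475711,-0.079119563145328753,-0.013695358096756382,-0.059222174457035683,1,-0.020409215600833044
-0.11793088351191305,0.020999626316178844,3.4166064534470186e-05,0.005159703234180372,0.0049694826919710628,-0.0804668175203056,-0.10265251385203836,0.061019288547388258,-0.020409215600833044,1
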