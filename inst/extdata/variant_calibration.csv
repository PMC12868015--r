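"lr_cost_mode","dr_cost_mode","event_timing","dead_accrues_routine","mortality_source_states","cost_bca_low","cost_bca_small","cost_bcs_low","cost_bcs_small","procedure_cost_threshold","qaly_bca_low","qaly_bcs_low","qaly_bcs_small","admissible","score"
"per_cycle","one_time_on_entry","entry_cycle",TRUE,"all_alive",175594.717231629,175594.717231629,191304.876066818,197048.536050237,21104.7082378387,3.49127699167568,3.46234149764918,3.38008714746043,FALSE,0.0158115528217416
"per_cycle","one_time_on_entry","entry_cycle",TRUE,"disease_free_only",175594.717231629,175594.717231629,191304.876066818,197048.536050237,21203.8279558318,3.49235423770768,3.46242754650125,3.38195127997469,FALSE,0.0167597946469892
"one_time_on_entry","per_cycle","entry_cycle",FALSE,"all_alive",175370.038119895,175370.038119895,191705.245127067,201817.037758572,21729.7564098222,3.49127699167568,3.46234149764918,3.38008714746043,TRUE,0.0167843938689878
"one_time_on_entry","per_cycle","entry_cycle",FALSE,"disease_free_only",175456.561392765,175456.561392765,191714.513846629,202091.446010322,21751.6215745069,3.49235423770768,3.46242754650125,3.38195127997469,TRUE,0.0169372073743829
"per_cycle","per_cycle","entry_cycle",TRUE,"disease_free_only",177627.725001839,177627.725001839,192376.731717862,205487.02284047,20242.675836666,3.49235423770768,3.46242754650125,3.38195127997469,FALSE,0.0176010919256451
"per_cycle","per_cycle","entry_cycle",TRUE,"all_alive",177592.783352741,177592.783352741,192371.668661254,205306.391340761,20173.4347111626,3.49127699167568,3.46234149764918,3.38008714746043,FALSE,0.0183523546225429
"one_time_on_entry","per_cycle","next_cycle",TRUE,"all_alive",177519.571741989,177519.571741989,191988.46803539,201196.751979275,21729.9125871335,3.51679829076581,3.46919812782848,3.41214954907383,TRUE,0.0226293831887269
"one_time_on_entry","per_cycle","next_cycle",TRUE,"disease_free_only",177537.020701855,177537.020701855,191990.985015911,201287.14806811,21764.4977828703,3.51733623969674,3.46924090500861,3.4130824444361,TRUE,0.0229156746585285
"one_time_on_entry","one_time_on_entry","entry_cycle",TRUE,"disease_free_only",177018.204145655,177018.204145655,191644.375021969,198093.795060573,20119.8399969568,3.49235423770768,3.46242754650125,3.38195127997469,TRUE,0.0237536588473301
"one_time_on_entry","one_time_on_entry","entry_cycle",TRUE,"all_alive",177018.204145655,177018.204145655,191644.375021969,198093.795060573,20020.7202789636,3.49127699167568,3.46234149764918,3.38008714746043,TRUE,0.0247019006725777
"per_cycle","per_cycle","entry_cycle",FALSE,"all_alive",173946.551205869,173946.551205869,191365.746171917,200771.778748236,22813.7443686972,3.49127699167568,3.46234149764918,3.38008714746043,FALSE,0.024705157550187
"per_cycle","per_cycle","entry_cycle",FALSE,"disease_free_only",174033.074478739,174033.074478739,191375.014891478,201046.186999986,22835.609533382,3.49235423770768,3.46242754650125,3.38195127997469,FALSE,0.0248386055473269
"per_cycle","per_cycle","next_cycle",TRUE,"all_alive",176388.110839539,176388.110839539,191720.276484173,200363.217657462,22593.1819383668,3.51679829076581,3.46919812782848,3.41214954907383,FALSE,0.0288088448176654
"one_time_on_entry","one_time_on_entry","next_cycle",TRUE,"all_alive",176397.352962433,176397.352962433,191392.931827581,196544.930326921,22256.5951588808,3.51679829076581,3.46919812782848,3.41214954907383,TRUE,0.0290736035790164
"per_cycle","per_cycle","next_cycle",TRUE,"disease_free_only",176405.559799404,176405.559799404,191722.793464694,200453.613746296,22627.7671341037,3.51733623969674,3.46924090500861,3.4130824444361,FALSE,0.0290951362874672
"one_time_on_entry","one_time_on_entry","next_cycle",TRUE,"disease_free_only",176397.352962433,176397.352962433,191392.931827581,196544.930326921,22306.112333962,3.51733623969674,3.46924090500861,3.4130824444361,TRUE,0.0295473161503476
"one_time_on_entry","per_cycle","entry_cycle",TRUE,"disease_free_only",179051.211915865,179051.211915865,192716.230673013,206532.281850806,19158.6878777909,3.49235423770768,3.46242754650125,3.38195127997469,TRUE,0.0305924113719205
"one_time_on_entry","per_cycle","entry_cycle",TRUE,"all_alive",179016.270266767,179016.270266767,192711.167616405,206351.650351097,19089.4467522875,3.49127699167568,3.46234149764918,3.38008714746043,TRUE,0.031343674068818
"one_time_on_entry","one_time_on_entry","entry_cycle",FALSE,"all_alive",173371.971998783,173371.971998783,190638.452532631,193559.182468047,22661.0299364982,3.49127699167568,3.46234149764918,3.38008714746043,TRUE,0.0314664046012459
"one_time_on_entry","one_time_on_entry","entry_cycle",FALSE,"disease_free_only",173423.553622555,173423.553622555,190642.658195585,193652.95922009,22712.7736936727,3.49235423770768,3.46242754650125,3.38195127997469,TRUE,0.0317476506356422
"per_cycle","one_time_on_entry","next_cycle",TRUE,"all_alive",175265.892059983,175265.892059983,191124.740276364,195711.396005107,23119.8645101141,3.51679829076581,3.46919812782848,3.41214954907383,FALSE,0.0358134085935573
"one_time_on_entry","per_cycle","next_cycle",FALSE,"all_alive",175107.471343706,175107.471343706,191324.159416897,198195.213709262,23477.7043669236,3.51679829076581,3.46919812782848,3.41214954907383,TRUE,0.0362631034016454
"per_cycle","one_time_on_entry","next_cycle",TRUE,"disease_free_only",175265.892059983,175265.892059983,191124.740276364,195711.396005107,23169.3816851954,3.51733623969674,3.46924090500861,3.4130824444361,FALSE,0.0362871211648887
"one_time_on_entry","per_cycle","next_cycle",FALSE,"disease_free_only",175150.678838335,175150.678838335,191328.767144678,198332.539882948,23488.6217751571,3.51733623969674,3.46924090500861,3.4130824444361,TRUE,0.0363294674653181
"per_cycle","per_cycle","next_cycle",FALSE,"all_alive",173976.010441256,173976.010441256,191055.96786568,197361.679387448,24340.973718157,3.51679829076581,3.46919812782848,3.41214954907383,FALSE,0.0430029084161865
"per_cycle","per_cycle","next_cycle",FALSE,"disease_free_only",174019.217935884,174019.217935884,191060.575593461,197499.005561135,24351.8911263904,3.51733623969674,3.46924090500861,3.4130824444361,FALSE,0.0430692724798589
"one_time_on_entry","one_time_on_entry","next_cycle",FALSE,"all_alive",173985.25256415,173985.25256415,190728.623209088,193543.392056907,24004.3869386709,3.51679829076581,3.46919812782848,3.41214954907383,TRUE,0.0438365453777243
"one_time_on_entry","one_time_on_entry","next_cycle",FALSE,"disease_free_only",174011.011098913,174011.011098913,190730.713956348,193590.322141759,24030.2363262487,3.51733623969674,3.46924090500861,3.4130824444361,TRUE,0.0440955893714763
"per_cycle","one_time_on_entry","entry_cycle",FALSE,"all_alive",171948.485084757,171948.485084757,190298.953577481,192513.923457711,23745.0178953733,3.49127699167568,3.46234149764918,3.38008714746043,FALSE,0.0464782217213084
"per_cycle","one_time_on_entry","entry_cycle",FALSE,"disease_free_only",172000.066708529,172000.066708529,190303.159240434,192607.700209754,23796.7616525478,3.49235423770768,3.46242754650125,3.38195127997469,FALSE,0.0467594677557046
"per_cycle","one_time_on_entry","next_cycle",FALSE,"all_alive",172853.791661699,172853.791661699,190460.431657871,192709.857735093,24867.6562899042,3.51679829076581,3.46919812782848,3.41214954907383,FALSE,0.054776059602585
"per_cycle","one_time_on_entry","next_cycle",FALSE,"disease_free_only",172879.550196463,172879.550196463,190462.522405131,192756.787819945,24893.5056774821,3.51733623969674,3.46924090500861,3.4130824444361,FALSE,0.0549165140689799
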