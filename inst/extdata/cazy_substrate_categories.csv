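family,category
GH2,animal carbohydrates
GH18,animal carbohydrates
GH20,animal carbohydrates
GH29,animal carbohydrates
GH33,animal carbohydrates
GH84,animal carbohydrates
GH85,animal carbohydrates
GH89,animal carbohydrates
GH95,animal carbohydrates
GH98,animal carbohydrates
GH101,animal carbohydrates
GH129,animal carbohydrates
GH5,plant cell wall
GH8,plant cell wall
GH9,plant cell wall
GH10,plant cell wall
GH26,plant cell wall
GH28,plant cell wall
GH43,plant cell wall
GH44,plant cell wall
GH45,plant cell wall
GH48,plant cell wall
GH51,plant cell wall
GH53,plant cell wall
GH54,plant cell wall
GH67,plant cell wall
GH74,plant cell wall
GH93,plant cell wall
GH115,plant cell wall
GH120,plant cell wall
PL1,plant cell wall
PL9,plant cell wall
PL11,plant cell wall
GH23,peptidoglycan
GH24,peptidoglycan
GH25,peptidoglycan
GH73,peptidoglycan
GH102,peptidoglycan
GH103,peptidoglycan
GH104,peptidoglycan
GH13,other
GH32,other
GH77,other
GT2,other
GT4,other
CE1,other
CE4,other
CBM50,other
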