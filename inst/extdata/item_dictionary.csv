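"instrument","item","domain","polarity","valid_range"
"qids","q1","sleep",NA,"0..3"
"qids","q2","sleep",NA,"0..3"
"qids","q3","sleep",NA,"0..3"
"qids","q4","sleep",NA,"0..3"
"qids","q5","mood",NA,"0..3"
"qids","q6","appetite_weight",NA,"0..3"
"qids","q7","appetite_weight",NA,"0..3"
"qids","q8","appetite_weight",NA,"0..3"
"qids","q9","appetite_weight",NA,"0..3"
"qids","q10","concentration",NA,"0..3"
"qids","q11","self_view",NA,"0..3"
"qids","q12","suicidal_ideation",NA,"0..3"
"qids","q13","interest",NA,"0..3"
"qids","q14","fatigue",NA,"0..3"
"qids","q15","psychomotor",NA,"0..3"
"qids","q16","psychomotor",NA,"0..3"
"bai","b1","anxiety",NA,"0..3"
"bai","b2","anxiety",NA,"0..3"
"bai","b3","anxiety",NA,"0..3"
"bai","b4","anxiety",NA,"0..3"
"bai","b5","anxiety",NA,"0..3"
"bai","b6","anxiety",NA,"0..3"
"bai","b7","anxiety",NA,"0..3"
"bai","b8","anxiety",NA,"0..3"
"bai","b9","anxiety",NA,"0..3"
"bai","b10","anxiety",NA,"0..3"
"bai","b11","anxiety",NA,"0..3"
"bai","b12","anxiety",NA,"0..3"
"bai","b13","anxiety",NA,"0..3"
"bai","b14","anxiety",NA,"0..3"
"bai","b15","anxiety",NA,"0..3"
"bai","b16","anxiety",NA,"0..3"
"bai","b17","anxiety",NA,"0..3"
"bai","b18","anxiety",NA,"0..3"
"bai","b19","anxiety",NA,"0..3"
"bai","b20","anxiety",NA,"0..3"
"bai","b21","anxiety",NA,"0..3"
"djg_loneliness","l1","loneliness","negative","yes|more_or_less|no"
"djg_loneliness","l2","loneliness","negative","yes|more_or_less|no"
"djg_loneliness","l3","loneliness","negative","yes|more_or_less|no"
"djg_loneliness","l4","loneliness","positive","yes|more_or_less|no"
"djg_loneliness","l5","loneliness","positive","yes|more_or_less|no"
"djg_loneliness","l6","loneliness","positive","yes|more_or_less|no"
"perceived_impact","impact_1","perceived_impact",NA,"1..5"
"perceived_impact","impact_2","perceived_impact",NA,"1..5"
"perceived_impact","impact_3","perceived_impact",NA,"1..5"
"perceived_impact","impact_4","perceived_impact",NA,"1..5"
"perceived_impact","impact_5","perceived_impact",NA,"1..5"
"perceived_impact","impact_6","perceived_impact",NA,"1..5"
"perceived_impact","impact_7","perceived_impact",NA,"1..5"
"perceived_impact","impact_8","perceived_impact",NA,"1..5"
"perceived_impact","impact_9","perceived_impact",NA,"1..5"
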