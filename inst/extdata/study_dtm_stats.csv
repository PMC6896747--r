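review,documents,tokens,n_nonzero,n_zero,sparsity
sr01,418,61208,147445,25437499,0.99
sr02,209,35821,73977,7412612,0.99
sr03,413,58351,125027,23963936,0.99
sr04,206,33851,68826,6904480,0.99
sr05,412,57485,138846,23544974,0.99
sr06,832,101418,288432,84091344,1.00
sr07,209,33389,69854,6908447,0.99
sr08,623,88108,219258,54672026,1.00
sr09,413,58133,141721,23869208,0.99
sr10,1675,187947,603479,314207746,1.00
sr11,209,33653,69130,6964347,0.99
sr12,414,59572,141105,24521703,0.99
sr13,418,54458,130782,22632662,0.99
sr14,1043,131172,370385,136442011,1.00
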