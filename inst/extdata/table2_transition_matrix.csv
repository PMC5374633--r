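# Fitted transition probabilities between the four behavioural dive states
# (rows: from-state; printed to 3 decimals, so rows sum to 1 within 0.005)
# and the number of dives allocated to each state, for the 20-whale
# short-finned pilot whale study off Cape Hatteras.
state,to_state1,to_state2,to_state3,to_state4,n_dives
1,0.526,0.168,0.275,0.030,59
2,0.040,0.714,0.134,0.112,57
3,0.142,0.087,0.730,0.041,112
4,0.069,0.148,0.140,0.643,31
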