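t_count,m_count,score
1,1,-0.0121
1,2,-0.0146
1,3,-0.0168
1,4,-0.0193
1,5,-0.0187
1,6,-0.0181
2,4,-0.0152
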