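gene	direction
MTF1_UP01	up
MTF1_UP02	up
MTF1_UP03	up
MTF1_UP04	up
MTF1_UP05	up
MTF1_UP06	up
MTF1_UP07	up
MTF1_UP08	up
MTF1_UP09	up
MTF1_UP10	up
MTF1_UP11	up
MTF1_UP12	up
MTF1_UP13	up
MTF1_UP14	up
MTF1_DN01	down
MTF1_DN02	down
MTF1_DN03	down
MTF1_DN04	down
MTF1_DN05	down
MTF1_DN06	down
MTF1_DN07	down
MTF1_DN08	down
MTF1_DN09	down
MTF1_DN10	down
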