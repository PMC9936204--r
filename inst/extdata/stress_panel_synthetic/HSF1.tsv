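gene	direction
HSF1_UP01	up
HSF1_UP02	up
HSF1_UP03	up
HSF1_UP04	up
HSF1_UP05	up
HSF1_UP06	up
HSF1_UP07	up
HSF1_UP08	up
HSF1_UP09	up
HSF1_UP10	up
HSF1_UP11	up
HSF1_UP12	up
HSF1_UP13	up
HSF1_UP14	up
HSF1_UP15	up
HSF1_DN01	down
HSF1_DN02	down
HSF1_DN03	down
HSF1_DN04	down
HSF1_DN05	down
HSF1_DN06	down
HSF1_DN07	down
HSF1_DN08	down
HSF1_DN09	down
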