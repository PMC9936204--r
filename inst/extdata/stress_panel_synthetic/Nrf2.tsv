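gene	direction
NRF2_UP01	up
NRF2_UP02	up
NRF2_UP03	up
NRF2_UP04	up
NRF2_UP05	up
NRF2_UP06	up
NRF2_UP07	up
NRF2_UP08	up
NRF2_UP09	up
NRF2_UP10	up
NRF2_UP11	up
NRF2_UP12	up
NRF2_UP13	up
NRF2_UP14	up
NRF2_UP15	up
NRF2_UP16	up
NRF2_DN01	down
NRF2_DN02	down
NRF2_DN03	down
NRF2_DN04	down
NRF2_DN05	down
NRF2_DN06	down
NRF2_DN07	down
NRF2_DN08	down
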