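gene	direction
NFKB_UP01	up
NFKB_UP02	up
NFKB_UP03	up
NFKB_UP04	up
NFKB_UP05	up
NFKB_UP06	up
NFKB_UP07	up
NFKB_UP08	up
NFKB_UP09	up
NFKB_UP10	up
NFKB_UP11	up
NFKB_UP12	up
NFKB_UP13	up
NFKB_UP14	up
NFKB_UP15	up
NFKB_UP16	up
NFKB_UP17	up
NFKB_UP18	up
NFKB_DN01	down
NFKB_DN02	down
NFKB_DN03	down
NFKB_DN04	down
NFKB_DN05	down
NFKB_DN06	down
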