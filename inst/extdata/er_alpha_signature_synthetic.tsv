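gene	direction
ERSIG_UP01	up
ERSIG_UP02	up
ERSIG_UP03	up
ERSIG_UP04	up
ERSIG_UP05	up
ERSIG_UP06	up
ERSIG_UP07	up
ERSIG_UP08	up
ERSIG_UP09	up
ERSIG_UP10	up
ERSIG_UP11	up
ERSIG_UP12	up
ERSIG_UP13	up
ERSIG_UP14	up
ERSIG_UP15	up
ERSIG_UP16	up
ERSIG_UP17	up
ERSIG_UP18	up
ERSIG_UP19	up
ERSIG_UP20	up
ERSIG_UP21	up
ERSIG_UP22	up
ERSIG_UP23	up
ERSIG_UP24	up
ERSIG_UP25	up
ERSIG_UP26	up
ERSIG_UP27	up
ERSIG_UP28	up
ERSIG_UP29	up
ERSIG_UP30	up
ERSIG_UP31	up
ERSIG_UP32	up
ERSIG_DN01	down
ERSIG_DN02	down
ERSIG_DN03	down
ERSIG_DN04	down
ERSIG_DN05	down
ERSIG_DN06	down
ERSIG_DN07	down
ERSIG_DN08	down
ERSIG_DN09	down
ERSIG_DN10	down
ERSIG_DN11	down
ERSIG_DN12	down
ERSIG_DN13	down
ERSIG_DN14	down
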