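gene	direction
TGXDDI_UP01	up
TGXDDI_UP02	up
TGXDDI_UP03	up
TGXDDI_UP04	up
TGXDDI_UP05	up
TGXDDI_UP06	up
TGXDDI_UP07	up
TGXDDI_UP08	up
TGXDDI_UP09	up
TGXDDI_UP10	up
TGXDDI_UP11	up
TGXDDI_UP12	up
TGXDDI_UP13	up
TGXDDI_UP14	up
TGXDDI_UP15	up
TGXDDI_UP16	up
TGXDDI_UP17	up
TGXDDI_UP18	up
TGXDDI_UP19	up
TGXDDI_UP20	up
TGXDDI_DN01	down
TGXDDI_DN02	down
TGXDDI_DN03	down
TGXDDI_DN04	down
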