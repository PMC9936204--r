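gene	direction
HDACI_UP01	up
HDACI_UP02	up
HDACI_UP03	up
HDACI_UP04	up
HDACI_UP05	up
HDACI_UP06	up
HDACI_UP07	up
HDACI_UP08	up
HDACI_UP09	up
HDACI_UP10	up
HDACI_UP11	up
HDACI_UP12	up
HDACI_DN01	down
HDACI_DN02	down
HDACI_DN03	down
HDACI_DN04	down
HDACI_DN05	down
HDACI_DN06	down
HDACI_DN07	down
HDACI_DN08	down
HDACI_DN09	down
HDACI_DN10	down
HDACI_DN11	down
HDACI_DN12	down
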