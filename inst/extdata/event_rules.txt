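# Disaster-specific filter rules for the five historical U.S. mass-casualty
# case studies (2012-2014). Format: <event code> TAB <rule text>.
# Events with two lines include a tweet when it matches either rule.
sh	School (gunman OR 'Sandy Hook' OR victims OR shooting OR Newtown)
sh	Newtown (shooting OR gunman OR student OR Sandy Hook OR elementary)
bb	Bomb (Boston OR marathon OR explosion OR terrorist OR finish line)
bb	Boston (explosion OR terrorist)
sf	Plane (crash OR SFO OR runway OR San Francisco OR Asiana OR '214')
sf	Asiana (Crash OR '214' OR Runway OR SFO OR San Francisco)
ne	Earthquake (San Francisco OR 'sf' OR Napa OR '6.0')
mv	School (gunman OR Marysville OR victims OR shooting OR Washington)
mv	Marysville (shooting OR gunman OR student)
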