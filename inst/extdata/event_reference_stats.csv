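event,total_tweets,peak_tpm_60,threshold200_minute,onset_local,tz
sh,1815751,209,NA,2012-12-14 09:35:00,America/New_York
bb,1147793,3326,7,2013-04-15 14:49:00,America/New_York
sf,430616,1423,18,2013-07-06 11:28:00,America/Los_Angeles
ne,205073,739,2,2014-08-24 03:20:44,America/Los_Angeles
mv,249847,957,NA,2014-10-24 10:39:00,America/Los_Angeles
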