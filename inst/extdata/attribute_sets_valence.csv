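set,word
positive,caress
positive,freedom
positive,health
positive,love
positive,peace
positive,cheer
positive,friend
positive,heaven
positive,loyal
positive,pleasure
positive,diamond
positive,gentle
positive,honest
positive,lucky
positive,rainbow
positive,diploma
positive,gift
positive,honor
positive,miracle
positive,sunrise
positive,family
positive,happy
positive,laughter
positive,paradise
positive,vacation
negative,abuse
negative,crash
negative,filth
negative,murder
negative,sickness
negative,accident
negative,death
negative,grief
negative,poison
negative,stink
negative,assault
negative,disaster
negative,hatred
negative,pollute
negative,tragedy
negative,divorce
negative,jail
negative,poverty
negative,ugly
negative,cancer
negative,kill
negative,rotten
negative,vomit
negative,agony
negative,prison
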