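# Negation trigger lexicon.
# Sections: [PRE] pre-negation triggers, [PSEUDO] pseudo-negations,
# [TERM] scope terminators. One phrase per line.

[PRE]
no
not
without
denies
denied
deny
negative for
no evidence of
no history of
no signs of
absence of
absent
free of
never had
never developed
rules out
ruled out
cannot

[PSEUDO]
not only
no increase
no change
no significant change
not necessarily
not certain if
not certain whether
gram negative
not rule out
not ruled out
no further

[TERM]
but
however
nevertheless
yet
though
although
except
apart from
aside from
still
other than
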