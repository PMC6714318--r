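# Default NegEx-style trigger lexicon: phrase<TAB>role
# roles: PRE (negates following terms), POST (negates preceding terms),
#        PSEUDO (ignored look-alikes), TERM (scope terminators)
no	PRE
not	PRE
without	PRE
denies	PRE
denied	PRE
deny	PRE
no evidence of	PRE
no sign of	PRE
no signs of	PRE
no history of	PRE
absence of	PRE
free of	PRE
negative for	PRE
never had	PRE
never developed	PRE
lack of	PRE
rules out	PRE
ruled out for	PRE
was ruled out	POST
were ruled out	POST
is ruled out	POST
are ruled out	POST
has been ruled out	POST
unlikely	POST
was not found	POST
no increase	PSEUDO
no change	PSEUDO
no significant change	PSEUDO
no further	PSEUDO
not certain if	PSEUDO
not certain whether	PSEUDO
not rule out	PSEUDO
not ruled out	PSEUDO
gram negative	PSEUDO
but	TERM
however	TERM
although	TERM
though	TERM
except	TERM
apart from	TERM
aside from	TERM
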