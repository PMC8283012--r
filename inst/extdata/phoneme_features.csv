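# pastnet phoneme feature inventory v1
# Binary articulatory features in {-1,+1}; consonants use f1..f7, vowels f1..f6 (f7 empty).
# Consonant features: f1 voice, f2 labial, f3 coronal, f4 dorsal, f5 continuant, f6 sonorant, f7 strident
# Vowel features:     f1 high,  f2 low,    f3 front,   f4 back,   f5 round,      f6 tense
# ASCII symbols: T=theta, D=eth, S=esh, Z=ezh, C=t-esh, J=d-ezh, N=eng, &=ash, A=script-a,
#                V=wedge, O=open-o, I/E/U=lax vowels, @=schwa, 3=open-mid central
symbol,class,voiced,alveolar_stop,f1,f2,f3,f4,f5,f6,f7
p,consonant,0,0,-1,1,-1,-1,-1,-1,-1
b,consonant,1,0,1,1,-1,-1,-1,-1,-1
t,consonant,0,1,-1,-1,1,-1,-1,-1,-1
d,consonant,1,1,1,-1,1,-1,-1,-1,-1
k,consonant,0,0,-1,-1,-1,1,-1,-1,-1
g,consonant,1,0,1,-1,-1,1,-1,-1,-1
f,consonant,0,0,-1,1,-1,-1,1,-1,1
v,consonant,1,0,1,1,-1,-1,1,-1,1
T,consonant,0,0,-1,-1,1,-1,1,-1,-1
D,consonant,1,0,1,-1,1,-1,1,-1,-1
s,consonant,0,0,-1,-1,1,-1,1,-1,1
z,consonant,1,0,1,-1,1,-1,1,-1,1
S,consonant,0,0,-1,-1,1,1,1,-1,1
Z,consonant,1,0,1,-1,1,1,1,-1,1
C,consonant,0,0,-1,-1,1,1,-1,-1,1
J,consonant,1,0,1,-1,1,1,-1,-1,1
m,consonant,1,0,1,1,-1,-1,-1,1,-1
n,consonant,1,0,1,-1,1,-1,-1,1,-1
N,consonant,1,0,1,-1,-1,1,-1,1,-1
l,consonant,1,0,1,-1,1,-1,1,1,-1
r,consonant,1,0,1,-1,1,1,1,1,-1
w,consonant,1,0,1,1,-1,1,1,1,-1
j,consonant,1,0,1,-1,-1,1,1,1,1
h,consonant,0,0,-1,-1,-1,1,1,-1,-1
i,vowel,1,0,1,-1,1,-1,-1,1,
I,vowel,1,0,1,-1,1,-1,-1,-1,
e,vowel,1,0,-1,-1,1,-1,-1,1,
E,vowel,1,0,-1,-1,1,-1,-1,-1,
&,vowel,1,0,-1,1,1,-1,-1,-1,
A,vowel,1,0,-1,1,-1,1,-1,1,
V,vowel,1,0,-1,-1,-1,1,-1,-1,
o,vowel,1,0,-1,-1,-1,1,1,1,
O,vowel,1,0,-1,1,-1,1,1,-1,
U,vowel,1,0,1,-1,-1,1,1,-1,
u,vowel,1,0,1,-1,-1,1,1,1,
@,vowel,1,0,-1,-1,-1,-1,-1,-1,
3,vowel,1,0,-1,-1,-1,-1,-1,1,
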