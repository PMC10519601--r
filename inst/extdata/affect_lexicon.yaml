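# Open affect lexicon covering the five analysis categories.
# Entries are literal lower-case words or stems with a trailing * wildcard.
posemo:
  - love
  - lovely
  - loving
  - nice
  - sweet
  - happ*
  - joy*
  - hope*
  - glad
  - good
  - great
  - awesome
  - wonderful
  - cheer*
anxiety:
  - worri*
  - fearful
  - fear
  - fears
  - anxi*
  - nervous
  - afraid
  - panic*
  - scared
  - tense
  - uneasy
anger:
  - hate*
  - hating
  - kill*
  - annoy*
  - angry
  - anger
  - furious
  - rage
  - mad
  - irritat*
sadness:
  - crying
  - cried
  - cries
  - cry
  - grief
  - griev*
  - sad
  - sadly
  - sadness
  - depress*
  - miserable
  - lonel*
  - tear*
i:
  - i
  - me
  - mine
  - my
  - myself
  - i'm
  - i've
  - i'll
  - i'd
  - im
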