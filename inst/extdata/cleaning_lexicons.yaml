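# Illustrative cleaning lexicons for IBD/distress social-media corpora.
# The relevance keywords are the standard IBD umbrella terms; the distress
# list is a small stand-in for a full curated distress lexicon (several
# hundred entries in production use) exposed through the same schema.
relevance:
  - crohn
  - ibd
  - colitis
  - inflammatory bowel disease
  - ileitis
  - ileoceceal
exclusions:
  - investor's business daily
  - my dog has
  - my cat has
distress:
  unigrams:
    - afraid
    - scared
    - anxious
    - anxiety
    - depressed
    - depression
    - crying
    - hopeless
    - overwhelmed
    - struggling
    - distress
    - worried
    - miserable
    - suffering
    - exhausted
    - terrified
    - lonely
    - nervous
    - panic
    - stressed
  phrases:
    - feel alone
    - hard to manage
    - so tired of this
    - cant cope
    - breaking down
    - fed up
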