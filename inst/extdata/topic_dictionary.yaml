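# Illustrative 8-topic IBD dictionary with per-topic false-positive phrases.
# Terms match as exact normalized tokens (multi-word entries as consecutive
# tokens); substring_terms match inside single tokens, which catches hashtag
# compounds such as #crohnsdisease. false_positives are phrases whose spans
# suppress overlapping topic matches (e.g. "tired of explaining" would
# otherwise put a post under symptoms because of "tired").
# Production deployments replace these lists with full curated dictionaries
# via the same YAML schema.
topics:
  symptoms:
    terms:
      - tired
      - flare
      - flares
      - flare ups
      - pain
      - diarrhea
      - cramping
      - fatigue
      - bleeding
      - nausea
      - symptoms
    false_positives:
      - tired of explaining
      - tired of people
  medication:
    terms:
      - medication
      - drug
      - stelara
      - prednisone
      - steroids
      - humira
      - remicade
      - biologics
      - mesalamine
    false_positives:
      - drug test
      - drug store
  nutrition:
    terms:
      - diet
      - fodmap
      - fiber
      - gluten
      - nutrition
      - alcohol
      - dairy
    false_positives:
      - diet coke
      - diet pepsi
  procedures:
    terms:
      - surgery
      - colonoscopy
      - endoscopy
      - resection
      - procedure
      - scope
    false_positives:
      - rocket surgery
      - brain surgery joke
  marijuana:
    terms:
      - pot
      - weed
      - marijuana
      - cannabis
      - cbd
      - edibles
    false_positives:
      - pot of coffee
      - pot roast
  stigma:
    terms:
      - awkward
      - stigma
      - taboo
      - embarrassing
      - ashamed
      - judged
    false_positives:
      - awkward silence
  ostomy:
    terms:
      - bag
      - ostomy
      - stoma
      - colostomy
      - ileostomy
      - pouch
    false_positives:
      - bag of chips
      - sleeping bag
  intimacy:
    terms:
      - date
      - dating
      - intimacy
      - partner
      - relationship
      - girlfriend
      - boyfriend
    false_positives:
      - date of birth
      - expiration date
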