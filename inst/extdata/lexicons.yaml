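# Editable lexicons for family-history extraction.
# Surface terms are matched lowercase. The cue inventories are supersets
# of the examples documented for the method; extend them freely.
family_members:
  Father: [father, fathers, dad, dads, daddy]
  Mother: [mother, mothers, mom, moms, mum, mommy]
  Parent: [parent, parents]
  Brother: [brother, brothers]
  Sister: [sister, sisters]
  Sibling: [sibling, siblings]
  Son: [son, sons]
  Daughter: [daughter, daughters]
  Child: [child, children, kid, kids]
  Grandfather: [grandfather, grandfathers, grandpa, granddad, grandad]
  Grandmother: [grandmother, grandmothers, grandma, granny]
  Grandparent: [grandparent, grandparents]
  Uncle: [uncle, uncles]
  Aunt: [aunt, aunts, auntie, aunty]
  Cousin: [cousin, cousins]
excluded_members: [spouse, spouses, wife, husband, nephew, nephews, niece, nieces]
first_degree: [Father, Mother, Parent, Brother, Sister, Sibling, Son, Daughter, Child]
second_degree: [Grandfather, Grandmother, Grandparent, Uncle, Aunt, Cousin]
# kinship composition: normalized context relative x normalized target
composition:
  "Mother|Sister": Aunt
  "Father|Sister": Aunt
  "Parent|Sister": Aunt
  "Mother|Brother": Uncle
  "Father|Brother": Uncle
  "Parent|Brother": Uncle
  "Mother|Mother": Grandmother
  "Mother|Father": Grandfather
  "Father|Mother": Grandmother
  "Father|Father": Grandfather
  "Parent|Mother": Grandmother
  "Parent|Father": Grandfather
  "Aunt|Son": Cousin
  "Aunt|Daughter": Cousin
  "Aunt|Child": Cousin
  "Uncle|Son": Cousin
  "Uncle|Daughter": Cousin
  "Uncle|Child": Cousin
cues:
  paternal:
    - paternal
    - patient's father
    - father's
    - father had
    - father has
    - paternal family history
  maternal:
    - maternal
    - patient's mother
    - mother's
    - mother had
    - mother has
    - maternal family history
  not_alive:
    - deceased
    - passed away
    - passed on
    - died
    - dead
    - death
    - no longer living
    - expired
  healthy:
    - healthy
    - good general health
    - good health
    - in good health
    - alive and well
    - living and well
    - doing well
    - no health problems
negation:
  triggers:
    - no family history of
    - no history of
    - not aware of
    - not significant
    - denies
    - denied
    - negative for
    - no evidence of
    - never had
    - without
    - free of
    - "no"
  termination: [but, however, although]
  scope_tokens: 6
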