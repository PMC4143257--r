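codes:
- code: husband
  class3: male-relative
  implied_sex: male
  spouse: yes
- code: son
  class3: male-relative
  implied_sex: male
  spouse: no
- code: son-in-law
  class3: male-relative
  implied_sex: male
  spouse: no
- code: father
  class3: male-relative
  implied_sex: male
  spouse: no
- code: brother
  class3: male-relative
  implied_sex: male
  spouse: no
- code: father-in-law
  class3: male-relative
  implied_sex: male
  spouse: no
- code: brother-in-law
  class3: male-relative
  implied_sex: male
  spouse: no
- code: cousin-male
  class3: male-relative
  implied_sex: male
  spouse: no
- code: uncle
  class3: male-relative
  implied_sex: male
  spouse: no
- code: nephew
  class3: male-relative
  implied_sex: male
  spouse: no
- code: wife
  class3: female-relative
  implied_sex: female
  spouse: yes
- code: daughter
  class3: female-relative
  implied_sex: female
  spouse: no
- code: daughter-in-law
  class3: female-relative
  implied_sex: female
  spouse: no
- code: mother
  class3: female-relative
  implied_sex: female
  spouse: no
- code: sister
  class3: female-relative
  implied_sex: female
  spouse: no
- code: sister-in-law
  class3: female-relative
  implied_sex: female
  spouse: no
- code: mother-in-law
  class3: female-relative
  implied_sex: female
  spouse: no
- code: cousin-female
  class3: female-relative
  implied_sex: female
  spouse: no
- code: aunt
  class3: female-relative
  implied_sex: female
  spouse: no
- code: niece
  class3: female-relative
  implied_sex: female
  spouse: no
- code: friend
  class3: non-relative
  implied_sex: ~
  spouse: no
- code: workmate
  class3: non-relative
  implied_sex: ~
  spouse: no
- code: neighbor
  class3: non-relative
  implied_sex: ~
  spouse: no
- code: other
  class3: other
  implied_sex: ~
  spouse: no
other_is_relative: yes
nomination_cap: 5
talk_freq_levels:
- never
- rarely
- sometimes
- often
residence_levels:
- same household
- same city
- other
bodyweight_levels:
- less
- similar
- more
activity_domains:
- communication
- snacks
- meals
- exercise
- walking_tasks
- meal_prep_shop
- tobacco_co_use
- health_talk
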