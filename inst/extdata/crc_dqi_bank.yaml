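# Default CRC-DQI item bank: the 10 retained knowledge items with their
# keyed answers, and the 8 retained goals/concerns (importance scale 0-10).
# Knowledge responses are stored and matched as option LABELS, never as
# positions, so reordering options cannot silently change scoring.
knowledge_items:
  - item_id: K01
    prompt: >-
      At what age do doctors usually recommend people start getting regular
      tests for colon cancer?
    options: ["30", "40", "50", "60"]
    correct_option: "50"
  - item_id: K02
    prompt: >-
      Out of every 100 people, about how many will get colon cancer some
      time in their lives?
    options: ["6", "25", "50", "75"]
    correct_option: "6"
  - item_id: K03
    prompt: >-
      Does having a colon cancer test result that is not normal always mean
      that a person has colon cancer?
    options: ["Yes", "No"]
    correct_option: "No"
  - item_id: K04
    prompt: >-
      How often do serious problems, such as serious bleeding or a tear in
      the colon, happen as a result of a colonoscopy?
    options: ["Almost always", "Often", "Sometimes", "Rarely"]
    correct_option: "Rarely"
  - item_id: K05
    prompt: >-
      For a person with an average risk for colon cancer, which test do
      doctors recommend be done every year?
    options: ["Stool blood test", "Sigmoidoscopy", "Colonoscopy", "Barium enema"]
    correct_option: "Stool blood test"
  - item_id: K06
    prompt: >-
      For a person with an average risk for colon cancer, which test do
      doctors recommend be done every 10 years?
    options: ["Stool blood test", "Sigmoidoscopy", "Colonoscopy", "Barium enema"]
    correct_option: "Colonoscopy"
  - item_id: K07
    prompt: >-
      How does regular testing for colon cancer change the chances that a
      person will die from colon cancer?
    options: ["Increases chance", "No change", "Decreases chance"]
    correct_option: "Decreases chance"
  - item_id: K08
    prompt: Which colon cancer test is least likely to miss a cancer?
    options: ["Stool blood test", "Sigmoidoscopy", "Colonoscopy", "Barium enema"]
    correct_option: "Colonoscopy"
  - item_id: K09
    prompt: >-
      If the results of a colon cancer test are normal, is it possible that
      a person could still have colon cancer?
    options: ["Yes", "No"]
    correct_option: "Yes"
  - item_id: K10
    prompt: >-
      Out of every 100 people, about how many will die of colon cancer?
    options: ["3", "20", "45", "70"]
    correct_option: "3"
goal_items:
  - goal_id: G01
    prompt: To know whether or not you have colon cancer
  - goal_id: G02
    prompt: To avoid a test where a tube is put into your rectum
  - goal_id: G03
    prompt: To avoid a test that can cause bleeding or a tear in the colon
  - goal_id: G04
    prompt: To try to find colon cancer or polyps early
  - goal_id: G05
    prompt: To choose a test that does not need to be done every year
  - goal_id: G06
    prompt: To choose a test that doesn't cost you a lot of money
  - goal_id: G07
    prompt: To avoid a test that may be painful
  - goal_id: G08
    prompt: >-
      To choose a test where you take medicine before the test that makes
      you sleepy
# The published brief version is five knowledge items; the membership was
# never published, so the shipped default is the first five items, flagged
# as a convention in all reports.
brief_subset: [K01, K02, K03, K04, K05]
# Goals entered as covariates of the preference model. G08 is retained in
# the instrument but is not part of the published multivariable model.
model_goals: [G01, G02, G03, G04, G05, G06, G07]
goal_scale: {min: 0, max: 10}
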