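# Demo vocabulary: inhaled muscarinic-antagonist products and an
# illustrative cardiac event grouping. Preferred-term membership is a small
# demonstration set, not a licensed MedDRA release; supply your own
# vocabulary file for real analyses.

drugs:
  tiotropium:
    class: LAMA
    ingredients: [tiotropium]
    synonyms:
      - tiotropium
      - tiotropium bromide
      - tiotropium bromide anhydrous
      - tiotropium bromide monohydrate
      - spiriva
  aclidinium:
    class: LAMA
    ingredients: [aclidinium]
    synonyms:
      - aclidinium
      - aclidinium bromide
      - tudorza pressair
  glycopyrronium:
    class: LAMA
    ingredients: [glycopyrronium]
    synonyms:
      - glycopyrronium
      - glycopyrronium bromide
      - glycopyrrolate
      - seebri
  umeclidinium:
    class: LAMA
    ingredients: [umeclidinium]
    synonyms:
      - umeclidinium
      - umeclidinium bromide
      - incruse ellipta
  ipratropium:
    class: SAMA
    ingredients: [ipratropium]
    synonyms:
      - ipratropium
      - ipratropium bromide
      - ipratropium bromide anhydrous
      - atrovent
  indacaterol:
    class: LABA
    ingredients: [indacaterol]
    synonyms: [indacaterol, indacaterol maleate, arcapta]
  formoterol:
    class: LABA
    ingredients: [formoterol]
    synonyms: [formoterol, formoterol fumarate]
  vilanterol:
    class: LABA
    ingredients: [vilanterol]
    synonyms: [vilanterol, vilanterol trifenatate]
  budesonide:
    class: ICS
    ingredients: [budesonide]
    synonyms: [budesonide]
  mometasone:
    class: ICS
    ingredients: [mometasone]
    synonyms: [mometasone, mometasone furoate]
  fluticasone_furoate:
    class: ICS
    ingredients: [fluticasone furoate]
    synonyms: [fluticasone furoate]
  glycopyrronium_indacaterol:
    ingredients: [glycopyrronium, indacaterol]
    synonyms:
      - glycopyrronium/indacaterol
      - indacaterol/glycopyrronium
      - utibron neohaler
      - ultibro breezhaler
  glycopyrronium_formoterol:
    ingredients: [glycopyrronium, formoterol]
    synonyms:
      - glycopyrrolate/formoterol
      - glycopyrronium/formoterol
      - bevespi aerosphere
  glycopyrronium_indacaterol_mometasone:
    ingredients: [glycopyrronium, indacaterol, mometasone]
    synonyms:
      - glycopyrronium/indacaterol/mometasone
      - indacaterol/glycopyrronium/mometasone
      - enerzair breezhaler
  glycopyrronium_formoterol_budesonide:
    ingredients: [glycopyrronium, formoterol, budesonide]
    synonyms:
      - budesonide/glycopyrrolate/formoterol
      - glycopyrronium/formoterol/budesonide
      - breztri aerosphere
  umeclidinium_vilanterol:
    ingredients: [umeclidinium, vilanterol]
    synonyms:
      - umeclidinium/vilanterol
      - anoro ellipta
  umeclidinium_vilanterol_fluticasone:
    ingredients: [umeclidinium, vilanterol, fluticasone furoate]
    synonyms:
      - fluticasone furoate/umeclidinium/vilanterol
      - umeclidinium/vilanterol/fluticasone furoate
      - trelegy ellipta

event_groups:
  cardiac_disorders:
    label: Cardiac disorders (SOC-like)
    terms:
      - atrial fibrillation
      - atrial flutter
      - arrhythmia
      - tachycardia
      - sinus tachycardia
      - supraventricular tachycardia
      - ventricular tachycardia
      - ventricular fibrillation
      - ventricular extrasystoles
      - bradycardia
      - palpitations
      - atrioventricular block
      - cardiac failure
      - cardiac failure congestive
      - cardiac failure acute
      - left ventricular failure
      - cardiogenic shock
      - myocardial infarction
      - acute myocardial infarction
      - acute coronary syndrome
      - angina pectoris
      - angina unstable
      - myocardial ischaemia
      - coronary artery disease
      - cardiac arrest
      - cardiac disorder
      - cardiomegaly
      - cardiomyopathy
      - myocarditis
      - pericarditis
      - pericardial effusion
      - mitral valve incompetence
  arrhythmias:
    label: Cardiac arrhythmias (SMQ-like)
    terms:
      - atrial fibrillation
      - atrial flutter
      - arrhythmia
      - tachycardia
      - sinus tachycardia
      - supraventricular tachycardia
      - ventricular tachycardia
      - ventricular fibrillation
      - ventricular extrasystoles
      - bradycardia
      - palpitations
      - atrioventricular block
  cardiac_failure:
    label: Cardiac failure (SMQ-like)
    terms:
      - cardiac failure
      - cardiac failure congestive
      - cardiac failure acute
      - left ventricular failure
      - cardiogenic shock
  ischaemic_heart_disease:
    label: Ischaemic heart disease (SMQ-like)
    terms:
      - myocardial infarction
      - acute myocardial infarction
      - acute coronary syndrome
      - angina pectoris
      - angina unstable
      - myocardial ischaemia
      - coronary artery disease

ingredient_classes:
  tiotropium: LAMA
  aclidinium: LAMA
  glycopyrronium: LAMA
  umeclidinium: LAMA
  ipratropium: SAMA
  indacaterol: LABA
  formoterol: LABA
  vilanterol: LABA
  budesonide: ICS
  mometasone: ICS
  fluticasone furoate: ICS
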