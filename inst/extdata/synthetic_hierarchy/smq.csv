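"smq_id","pt","scope"
"embolic and thrombotic events","embolism venous","narrow"
"embolic and thrombotic events","thrombosis","narrow"
"embolic and thrombotic events","vascular occlusion","narrow"
"embolic and thrombotic events","deep vein thrombosis","narrow"
"embolic and thrombotic events","pulmonary embolism","narrow"
"embolic and thrombotic events","cerebral infarction","narrow"
"embolic and thrombotic events","portal vein thrombosis","narrow"
"anaphylactic reactions","anaphylactic reaction","narrow"
"anaphylactic reactions","anaphylactic shock","narrow"
"anaphylactic reactions","anaphylactoid reaction","narrow"
"anaphylactic reactions","hypersensitivity","broad"
"anaphylactic reactions","drug hypersensitivity","broad"
"anaphylactic reactions","urticaria","broad"
"anaphylactic reactions","bronchospasm","broad"
"hypersensitivity","hypersensitivity","narrow"
"hypersensitivity","drug hypersensitivity","narrow"
"hypersensitivity","urticaria","narrow"
"hypersensitivity","anaphylactic reaction","broad"
"hypersensitivity","anaphylactoid reaction","broad"
"hypersensitivity","rash","broad"
"hypersensitivity","dermatitis","broad"
"lack of efficacy/effect","drug ineffective","narrow"
"lack of efficacy/effect","therapeutic response decreased","narrow"
"lack of efficacy/effect","treatment failure","narrow"
"hyperglycaemia/new onset diabetes mellitus","hyperglycaemia","narrow"
"hyperglycaemia/new onset diabetes mellitus","diabetic ketoacidosis","narrow"
"hyperglycaemia/new onset diabetes mellitus","blood glucose increased","narrow"
"hypoglycaemia","hypoglycaemia","narrow"
"hypoglycaemia","hypoglycaemic coma","narrow"
"hypoglycaemia","blood glucose decreased","narrow"
"medication errors","medication error","narrow"
"medication errors","incorrect dose administered","narrow"
"medication errors","drug administration error","narrow"
"medication errors","overdose","narrow"
"medication errors","underdose","narrow"
"medication errors","accidental overdose","narrow"
"medication errors","device use error","narrow"
"medication errors","wrong technique in product usage process","narrow"
"medication errors","product preparation error","narrow"
"drug abuse and dependence","drug abuse","narrow"
"drug abuse and dependence","drug dependence","narrow"
"drug abuse and dependence","drug withdrawal syndrome","narrow"
"drug abuse and dependence","intentional product misuse","narrow"
"torsade de pointes/qt prolongation","torsade de pointes","narrow"
"torsade de pointes/qt prolongation","electrocardiogram qt prolonged","narrow"
"torsade de pointes/qt prolongation","ventricular tachycardia","narrow"
"torsade de pointes/qt prolongation","cardiac arrest","broad"
"psychosis and psychotic disorders","psychotic disorder","narrow"
"psychosis and psychotic disorders","hallucination","narrow"
"psychosis and psychotic disorders","paranoia","narrow"
"psychosis and psychotic disorders","schizophrenia","narrow"
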