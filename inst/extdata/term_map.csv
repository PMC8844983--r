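# Default condition-label -> ICD-10 term map.
# One row per label pattern; icd_codes holds one or more canonical ICD-10
# codes separated by ";". Lookup is case- and whitespace-insensitive.
# The first block carries the study's coding conventions (Burnout coded as
# a depressive disorder; functional somatic syndromes coded as somatoform
# disorders, F45; agoraphobia and panic-disorder suggestions credited
# against agoraphobia with panic disorder). The rest is a conventional
# label->code table for common mental-disorder terms.
label_pattern,icd_codes,note
burnout,F32,coded as depressive disorder
irritable bowel syndrome,F45,functional somatic syndrome
fibromyalgia,F45,functional somatic syndrome
chronic fatigue syndrome,F45,functional somatic syndrome
functional somatic syndrome,F45,functional somatic syndrome
tension headache,F45,functional somatic syndrome
agoraphobia,F40.00,ICD-10 chapter V
agoraphobia with panic disorder,F40.01,ICD-10 chapter V
panic disorder,F41.0,ICD-10 chapter V
social phobia,F40.1,ICD-10 chapter V
social anxiety disorder,F40.1,synonym of social phobia
specific phobia,F40.2,ICD-10 chapter V
generalized anxiety disorder,F41.1,ICD-10 chapter V
mixed anxiety and depressive disorder,F41.2,ICD-10 chapter V
depression,F32,generic depressive episode
depressive episode,F32,ICD-10 chapter V
major depressive disorder,F32.2,ICD-10 chapter V
recurrent depressive disorder,F33,ICD-10 chapter V
dysthymia,F34.1,ICD-10 chapter V
bipolar affective disorder,F31,ICD-10 chapter V
obsessive-compulsive disorder,F42,ICD-10 chapter V
post-traumatic stress disorder,F43.1,ICD-10 chapter V
posttraumatic stress disorder,F43.1,spelling variant
adjustment disorder,F43.2,ICD-10 chapter V
somatization disorder,F45.0,ICD-10 chapter V
hypochondriasis,F45.2,ICD-10 chapter V
somatoform autonomic dysfunction,F45.3,ICD-10 chapter V
anorexia nervosa,F50.0,ICD-10 chapter V
bulimia nervosa,F50.2,ICD-10 chapter V
insomnia,F51.0,nonorganic insomnia
alcohol abuse,F10.1,harmful use
alcohol addiction,F10.2,dependence syndrome
alcohol dependence,F10.2,dependence syndrome
cannabis abuse,F12.1,harmful use
cannabis addiction,F12.2,dependence syndrome
schizophrenia,F20,ICD-10 chapter V
attention deficit hyperactivity disorder,F90.0,ICD-10 chapter V
conduct disorder,F91,ICD-10 chapter V
borderline personality disorder,F60.31,ICD-10 chapter V
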