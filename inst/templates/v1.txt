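You are an experienced clinical geneticist asked to work up a diagnostically
challenging case. Review the clinical vignette below and provide your
differential diagnosis as a numbered list of candidate diagnoses, most likely first.
Reply with disease names only, one per line, and do not add commentary
after the list.

The case concerns {{sex_phrase}}.{{onset_sentence}}{{encounter_sentence}}

{{observed_block}}{{excluded_block}}
What is your differential diagnosis?
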