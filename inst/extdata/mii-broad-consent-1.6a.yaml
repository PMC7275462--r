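# Broad-consent template definition, version 1.6a.
# Four sections with a total of eight opt-in statements; every module offers
# the choices "Yes" and "No". Statement texts are abridged paraphrases.
version: "1.6a"
name: "Broad consent for the use of health data and biosamples"
sections:
  - "Use of clinical routine data"
  - "Use of health insurance data"
  - "Use of leftover or add-on biosamples"
  - "Permission to re-contact"
modules:
  - id: mdat_collection
    section: "Use of clinical routine data"
    statement: >-
      I consent to the collection, processing, storage and scientific use of
      my clinical routine data as described in the patient information.
    opt_in_choices: ["Yes", "No"]
  - id: mdat_transfer
    section: "Use of clinical routine data"
    statement: >-
      I consent to the transfer of my clinical routine data to other
      institutions for medical research purposes.
    opt_in_choices: ["Yes", "No"]
  - id: kkdat_retro
    section: "Use of health insurance data"
    statement: >-
      I consent to the retrospective retrieval and scientific use of data
      held by my health insurance provider, for a maximum of five years.
    opt_in_choices: ["Yes", "No"]
  - id: kkdat_prosp
    section: "Use of health insurance data"
    statement: >-
      I consent to the prospective retrieval and scientific use of data held
      by my health insurance provider, for a maximum of five years.
    opt_in_choices: ["Yes", "No"]
  - id: biomat_collection
    section: "Use of leftover or add-on biosamples"
    statement: >-
      I consent to the storage and scientific use of leftover biosamples
      taken in the course of my treatment.
    opt_in_choices: ["Yes", "No"]
  - id: biomat_addon
    section: "Use of leftover or add-on biosamples"
    statement: >-
      I consent to the collection of small additional sample quantities
      during routine procedures for scientific use.
    opt_in_choices: ["Yes", "No"]
  - id: recontact_research
    section: "Permission to re-contact"
    statement: >-
      I consent to being contacted again for information about further
      medical research projects.
    opt_in_choices: ["Yes", "No"]
  - id: recontact_info
    section: "Permission to re-contact"
    statement: >-
      I consent to being contacted again to obtain additional information
      or findings relevant to my health.
    opt_in_choices: ["Yes", "No"]
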