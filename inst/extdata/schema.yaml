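# Column dictionaries for the four qualstab input tables (CSV).
# Authoritative definitions live in the package (qualstab:::table_schemas()).
facilities:
  description: one row per facility x survey wave
  columns:
    facility_id: unique facility identifier (string)
    wave: survey wave year (integer)
    pair_set: label of the wave pair the facility was sampled for
    tier: hospital | health_centre | health_post
    authority: public | private
    region: administrative region label
    major_region: West | Centre | North | South
    urbanicity: urban | rural
    facility_weight: design weight, inverse tier sampling fraction (> 0)
  unique_key: [facility_id, wave]
readiness_items:
  description: long item responses, incl. the 7 BEmONC signal functions
  columns:
    facility_id: facility identifier
    wave: survey wave year
    instrument: readiness_general | readiness_anc | readiness_obstetric |
      readiness_child | bemonc
    item_id: registry item identifier
    response: 1 present/performed, 0 absent, empty = not assessed
visits:
  description: long action format, one row per observed visit x action
  columns:
    visit_id: unique visit identifier
    facility_id: facility identifier
    wave: survey wave year
    service: ANC | child
    visit_order: first | follow_up_2 | follow_up_3 | follow_up_4plus (ANC only)
    client_weight: inverse within-facility sampling fraction (> 0)
    action_id: registry action identifier
    response: 1 done, 0 not done, empty = not assessed
households:
  description: one row per in-need woman or child
  columns:
    unit_id: unique unit identifier
    unit_type: woman_live_birth_2y | child_under5_symptomatic_2w
    major_region: West | Centre | North | South
    survey_year: DHS interview year
    anc_sources: semicolon-separated reported ANC sources (women)
    anc_visits: number of ANC visits (women)
    delivery_source: reported delivery source (women)
    child_source: reported care source for the sick child (children)
    survey_weight: household survey weight (> 0)
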