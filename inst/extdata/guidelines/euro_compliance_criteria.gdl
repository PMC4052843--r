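guideline_id = <"stroke.euro_compliance_criteria">
description = <"Sample of compliance criteria from European guidelines for ischaemic stroke management: MRI justification, thrombolysis indication, temperature monitoring with a 37.5 degree Celsius pyrexia alert, and oxygen administration below 95% saturation.">
definitions = <
    gt0003 = <
        archetype_id = <"openEHR-EHR-EVALUATION.problem_diagnosis">
        path = <"/data[at0001]/items[at0002.1]">
        direction = <"input">
    >
    gt0004 = <
        archetype_id = <"openEHR-EHR-EVALUATION.problem_diagnosis">
        path = <"/data[at0001]/items[at0003]">
        direction = <"input">
    >
    gt0020 = <
        archetype_id = <"openEHR-EHR-OBSERVATION.exam">
        path = <"/data[at0001]/items[at0003]">
        direction = <"input">
    >
    gt0021 = <
        archetype_id = <"openEHR-EHR-INSTRUCTION.imaging">
        path = <"/activities[at0001]/description[at0002]/items[at0003]">
        direction = <"input">
    >
    gt0022 = <
        archetype_id = <"openEHR-EHR-OBSERVATION.body_temperature">
        path = <"/data[at0002]/items[at0004]">
        direction = <"input">
    >
    gt0023 = <
        archetype_id = <"openEHR-EHR-OBSERVATION.body_temperature">
        path = <"/data[at0002]/items[at0021]">
        direction = <"input">
    >
    gt0024 = <
        archetype_id = <"openEHR-EHR-OBSERVATION.indirect_oximetry">
        path = <"/data[at0001]/items[at0006]">
        direction = <"input">
    >
    gt9101 = <
        archetype_id = <"openEHR-EHR-EVALUATION.alert">
        path = <"/data[at0001]/items[at0010]">
        direction = <"output">
    >
    gt9102 = <
        archetype_id = <"openEHR-EHR-EVALUATION.alert">
        path = <"/data[at0001]/items[at0011]">
        direction = <"output">
    >
    gt9103 = <
        archetype_id = <"openEHR-EHR-EVALUATION.alert">
        path = <"/data[at0001]/items[at0012]">
        direction = <"output">
    >
    gt9104 = <
        archetype_id = <"openEHR-EHR-EVALUATION.alert">
        path = <"/data[at0001]/items[at0013]">
        direction = <"output">
    >
    gt9105 = <
        archetype_id = <"openEHR-EHR-ITEM_TREE.gas_administration">
        path = <"/items[at0001]">
        direction = <"output">
    >
    gt9106 = <
        archetype_id = <"openEHR-EHR-ITEM_TREE.gas_administration">
        path = <"/items[at0002]">
        direction = <"output">
    >
>
term_groups = <
    gt0102 = <"stroke">
    gt0201 = <"posterior circulation variety or uncommon aetiology">
    gt0202 = <"suspected stroke mimic">
    gt0203 = <"deficit related to acute cerebral ischaemia">
>
rules = <
    mri_exam_justified = <
        priority = <10>
        when = <"$gt0020 is_a local::gt0201|posterior circulation variety or uncommon aetiology|">
        then = <"$gt9101=true">
    >
    mri_imaging_justified = <
        priority = <10>
        when = <"$gt0021 is_a local::gt0202|suspected stroke mimic|">
        then = <"$gt9101=true">
    >
    thrombolysis_indicated = <
        priority = <10>
        when = <"$gt0020 is_a local::gt0203|deficit related to acute cerebral ischaemia|", "$gt0003 is_a local::gt0102|stroke|", "$gt0004+PT4H30M>currentDateTime">
        then = <"$gt9102=true">
    >
    temp_monitored = <
        priority = <10>
        when = <"$gt0003 is_a local::gt0102|stroke|", "$gt0023>=$gt0004", "$gt0023<$gt0004+PT72H">
        then = <"$gt9103=true">
    >
    pyrexia_alert = <
        priority = <10>
        when = <"$gt0003 is_a local::gt0102|stroke|", "$gt0022>37.5", "$gt0023>=$gt0004", "$gt0023<$gt0004+PT72H">
        then = <"$gt9104=true">
    >
    oxygen_recommended = <
        priority = <10>
        when = <"$gt0024<95">
        then = <"$gt9105=SNOMED-CT::24099007|Oxygen|", "$gt9106=local::at0006|Nasal canula|">
    >
>
terminology = <
    ICD10 = <
        gt0102 = <"I64">
    >
    ["SNOMED-CT"] = <
        gt0102 = <"230690007">
        gt0201 = <"95460007", "472916000">
        gt0202 = <"709491003">
        gt0203 = <"432504007">
    >
>
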