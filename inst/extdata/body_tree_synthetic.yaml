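- name: root
- name: background
  parent: root
  kind: background
- name: body
  parent: root
- name: subcutaneous tissue
  parent: body
- name: muscles
  parent: body
- name: bones
  parent: body
- name: thoracic cavity
  parent: body
- name: abdominal cavity
  parent: body
- name: brain
  parent: body
- name: spinal cord
  parent: body
- name: body other
  parent: body
  kind: other
- name: autochthon
  parent: muscles
- name: autochthon left
  parent: autochthon
- name: autochthon right
  parent: autochthon
- name: iliopsoas
  parent: muscles
- name: iliopsoas left
  parent: iliopsoas
- name: iliopsoas right
  parent: iliopsoas
- name: gluteus maximus
  parent: muscles
- name: gluteus maximus left
  parent: gluteus maximus
- name: gluteus maximus right
  parent: gluteus maximus
- name: gluteus medius
  parent: muscles
- name: gluteus medius left
  parent: gluteus medius
- name: gluteus medius right
  parent: gluteus medius
- name: gluteus minimus
  parent: muscles
- name: gluteus minimus left
  parent: gluteus minimus
- name: gluteus minimus right
  parent: gluteus minimus
- name: muscles other
  parent: muscles
  kind: other
- name: vertebrae
  parent: bones
- name: cervical vertebrae
  parent: vertebrae
- name: vertebra C1
  parent: cervical vertebrae
- name: vertebra C2
  parent: cervical vertebrae
- name: vertebra C3
  parent: cervical vertebrae
- name: vertebra C4
  parent: cervical vertebrae
- name: vertebra C5
  parent: cervical vertebrae
- name: vertebra C6
  parent: cervical vertebrae
- name: vertebra C7
  parent: cervical vertebrae
- name: thoracic vertebrae
  parent: vertebrae
- name: vertebra T1
  parent: thoracic vertebrae
- name: vertebra T2
  parent: thoracic vertebrae
- name: vertebra T3
  parent: thoracic vertebrae
- name: vertebra T4
  parent: thoracic vertebrae
- name: vertebra T5
  parent: thoracic vertebrae
- name: vertebra T6
  parent: thoracic vertebrae
- name: vertebra T7
  parent: thoracic vertebrae
- name: vertebra T8
  parent: thoracic vertebrae
- name: vertebra T9
  parent: thoracic vertebrae
- name: vertebra T10
  parent: thoracic vertebrae
- name: vertebra T11
  parent: thoracic vertebrae
- name: vertebra T12
  parent: thoracic vertebrae
- name: lumbar vertebrae
  parent: vertebrae
- name: vertebra L1
  parent: lumbar vertebrae
- name: vertebra L2
  parent: lumbar vertebrae
- name: vertebra L3
  parent: lumbar vertebrae
- name: vertebra L4
  parent: lumbar vertebrae
- name: vertebra L5
  parent: lumbar vertebrae
- name: ribs
  parent: bones
- name: ribs left
  parent: ribs
- name: rib left 1
  parent: ribs left
- name: rib left 2
  parent: ribs left
- name: rib left 3
  parent: ribs left
- name: rib left 4
  parent: ribs left
- name: rib left 5
  parent: ribs left
- name: rib left 6
  parent: ribs left
- name: rib left 7
  parent: ribs left
- name: rib left 8
  parent: ribs left
- name: rib left 9
  parent: ribs left
- name: rib left 10
  parent: ribs left
- name: rib left 11
  parent: ribs left
- name: rib left 12
  parent: ribs left
- name: ribs right
  parent: ribs
- name: rib right 1
  parent: ribs right
- name: rib right 2
  parent: ribs right
- name: rib right 3
  parent: ribs right
- name: rib right 4
  parent: ribs right
- name: rib right 5
  parent: ribs right
- name: rib right 6
  parent: ribs right
- name: rib right 7
  parent: ribs right
- name: rib right 8
  parent: ribs right
- name: rib right 9
  parent: ribs right
- name: rib right 10
  parent: ribs right
- name: rib right 11
  parent: ribs right
- name: rib right 12
  parent: ribs right
- name: sternum
  parent: bones
- name: sacrum
  parent: bones
- name: clavicula
  parent: bones
- name: clavicula left
  parent: clavicula
- name: clavicula right
  parent: clavicula
- name: scapula
  parent: bones
- name: scapula left
  parent: scapula
- name: scapula right
  parent: scapula
- name: humerus
  parent: bones
- name: humerus left
  parent: humerus
- name: humerus right
  parent: humerus
- name: hip
  parent: bones
- name: hip left
  parent: hip
- name: hip right
  parent: hip
- name: femur
  parent: bones
- name: femur left
  parent: femur
- name: femur right
  parent: femur
- name: bones other
  parent: bones
  kind: other
- name: lungs
  parent: thoracic cavity
- name: lung left
  parent: lungs
- name: lung upper lobe left
  parent: lung left
- name: lung lower lobe left
  parent: lung left
- name: lung right
  parent: lungs
- name: lung upper lobe right
  parent: lung right
- name: lung middle lobe right
  parent: lung right
- name: lung lower lobe right
  parent: lung right
- name: mediastinum
  parent: thoracic cavity
- name: pericardium
  parent: mediastinum
- name: heart
  parent: pericardium
- name: heart myocardium
  parent: heart
- name: heart atrium left
  parent: heart
- name: heart atrium right
  parent: heart
- name: heart ventricle left
  parent: heart
- name: heart ventricle right
  parent: heart
- name: aorta thoracica pass pericardium
  parent: pericardium
- name: pulmonary artery pass pericardium
  parent: pericardium
- name: inferior vena cava pass pericardium
  parent: pericardium
- name: pericardium other
  parent: pericardium
  kind: other
- name: great vessels mediastinum
  parent: mediastinum
- name: aorta thoracica pass mediastinum
  parent: great vessels mediastinum
- name: pulmonary artery pass mediastinum
  parent: great vessels mediastinum
- name: esophagus
  parent: mediastinum
- name: trachea
  parent: mediastinum
- name: mediastinum other
  parent: mediastinum
  kind: other
- name: thoracic cavity other
  parent: thoracic cavity
  kind: other
- name: liver
  parent: abdominal cavity
- name: spleen
  parent: abdominal cavity
- name: pancreas
  parent: abdominal cavity
- name: gastrointestinal tract
  parent: abdominal cavity
- name: stomach
  parent: gastrointestinal tract
- name: duodenum
  parent: gastrointestinal tract
- name: intestine
  parent: gastrointestinal tract
- name: colon
  parent: gastrointestinal tract
- name: kidney
  parent: abdominal cavity
- name: kidney left
  parent: kidney
- name: kidney right
  parent: kidney
- name: adrenal gland
  parent: abdominal cavity
- name: adrenal gland left
  parent: adrenal gland
- name: adrenal gland right
  parent: adrenal gland
- name: urinary bladder
  parent: abdominal cavity
- name: aorta abdominalis
  parent: abdominal cavity
- name: inferior vena cava abdominalis
  parent: abdominal cavity
- name: portal and splenic vein
  parent: abdominal cavity
- name: abdominal cavity other
  parent: abdominal cavity
  kind: other
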