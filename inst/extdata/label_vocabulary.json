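[{"id":1,"name":"liver","compartment":"reference","region":null,"region_id":null},{"id":2,"name":"aorta_thoracic","compartment":"reference","region":null,"region_id":null},{"id":3,"name":"aorta_abdominal","compartment":"reference","region":null,"region_id":null},{"id":4,"name":"kidney_left","compartment":"excretory","region":null,"region_id":null},{"id":5,"name":"kidney_right","compartment":"excretory","region":null,"region_id":null},{"id":6,"name":"urinary_bladder","compartment":"excretory","region":null,"region_id":null},{"id":7,"name":"prostate","compartment":"visceral","region":null,"region_id":null},{"id":8,"name":"lung_left","compartment":"visceral","region":null,"region_id":null},{"id":9,"name":"lung_right","compartment":"visceral","region":null,"region_id":null},{"id":11,"name":"femur","compartment":"bone","region":"femur","region_id":11},{"id":12,"name":"pelvic region","compartment":"bone","region":"pelvic region","region_id":12},{"id":13,"name":"lumbar vertebrae","compartment":"bone","region":"lumbar vertebrae","region_id":13},{"id":14,"name":"thoracic vertebrae","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":15,"name":"thorax","compartment":"bone","region":"thorax","region_id":15},{"id":101,"name":"femur_left","compartment":"bone","region":"femur","region_id":11},{"id":102,"name":"femur_right","compartment":"bone","region":"femur","region_id":11},{"id":103,"name":"hip_left","compartment":"bone","region":"pelvic region","region_id":12},{"id":104,"name":"hip_right","compartment":"bone","region":"pelvic region","region_id":12},{"id":105,"name":"sacrum","compartment":"bone","region":"pelvic region","region_id":12},{"id":106,"name":"vertebra_L1","compartment":"bone","region":"lumbar vertebrae","region_id":13},{"id":107,"name":"vertebra_L2","compartment":"bone","region":"lumbar vertebrae","region_id":13},{"id":108,"name":"vertebra_L3","compartment":"bone","region":"lumbar vertebrae","region_id":13},{"id":109,"name":"vertebra_L4","compartment":"bone","region":"lumbar vertebrae","region_id":13},{"id":110,"name":"vertebra_L5","compartment":"bone","region":"lumbar vertebrae","region_id":13},{"id":111,"name":"vertebra_T1","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":112,"name":"vertebra_T2","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":113,"name":"vertebra_T3","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":114,"name":"vertebra_T4","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":115,"name":"vertebra_T5","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":116,"name":"vertebra_T6","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":117,"name":"vertebra_T7","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":118,"name":"vertebra_T8","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":119,"name":"vertebra_T9","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":120,"name":"vertebra_T10","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":121,"name":"vertebra_T11","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":122,"name":"vertebra_T12","compartment":"bone","region":"thoracic vertebrae","region_id":14},{"id":123,"name":"rib_left_1","compartment":"bone","region":"thorax","region_id":15},{"id":124,"name":"rib_left_2","compartment":"bone","region":"thorax","region_id":15},{"id":125,"name":"rib_left_3","compartment":"bone","region":"thorax","region_id":15},{"id":126,"name":"rib_left_4","compartment":"bone","region":"thorax","region_id":15},{"id":127,"name":"rib_left_5","compartment":"bone","region":"thorax","region_id":15},{"id":128,"name":"rib_left_6","compartment":"bone","region":"thorax","region_id":15},{"id":129,"name":"rib_left_7","compartment":"bone","region":"thorax","region_id":15},{"id":130,"name":"rib_left_8","compartment":"bone","region":"thorax","region_id":15},{"id":131,"name":"rib_left_9","compartment":"bone","region":"thorax","region_id":15},{"id":132,"name":"rib_left_10","compartment":"bone","region":"thorax","region_id":15},{"id":133,"name":"rib_left_11","compartment":"bone","region":"thorax","region_id":15},{"id":134,"name":"rib_left_12","compartment":"bone","region":"thorax","region_id":15},{"id":135,"name":"rib_right_1","compartment":"bone","region":"thorax","region_id":15},{"id":136,"name":"rib_right_2","compartment":"bone","region":"thorax","region_id":15},{"id":137,"name":"rib_right_3","compartment":"bone","region":"thorax","region_id":15},{"id":138,"name":"rib_right_4","compartment":"bone","region":"thorax","region_id":15},{"id":139,"name":"rib_right_5","compartment":"bone","region":"thorax","region_id":15},{"id":140,"name":"rib_right_6","compartment":"bone","region":"thorax","region_id":15},{"id":141,"name":"rib_right_7","compartment":"bone","region":"thorax","region_id":15},{"id":142,"name":"rib_right_8","compartment":"bone","region":"thorax","region_id":15},{"id":143,"name":"rib_right_9","compartment":"bone","region":"thorax","region_id":15},{"id":144,"name":"rib_right_10","compartment":"bone","region":"thorax","region_id":15},{"id":145,"name":"rib_right_11","compartment":"bone","region":"thorax","region_id":15},{"id":146,"name":"rib_right_12","compartment":"bone","region":"thorax","region_id":15},{"id":147,"name":"sternum","compartment":"bone","region":"thorax","region_id":15},{"id":148,"name":"clavicle_left","compartment":"bone","region":"thorax","region_id":15},{"id":149,"name":"clavicle_right","compartment":"bone","region":"thorax","region_id":15},{"id":150,"name":"scapula_left","compartment":"bone","region":"thorax","region_id":15},{"id":151,"name":"scapula_right","compartment":"bone","region":"thorax","region_id":15}]
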