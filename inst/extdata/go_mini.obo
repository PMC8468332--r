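format-version: 1.2
data-version: synthetic-mini/2026-01
remark: Synthetic miniature GO subset (is_a edges only) for generator and tests.

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0002376
name: immune system process
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0006952
name: defense response
namespace: biological_process
is_a: GO:0002376 ! immune system process

[Term]
id: GO:0042742
name: defense response to bacterium
namespace: biological_process
is_a: GO:0006952 ! defense response

[Term]
id: GO:0051607
name: defense response to virus
namespace: biological_process
is_a: GO:0006952 ! defense response

[Term]
id: GO:0050832
name: defense response to fungus
namespace: biological_process
is_a: GO:0006952 ! defense response

[Term]
id: GO:0045087
name: innate immune response
namespace: biological_process
is_a: GO:0006952 ! defense response

[Term]
id: GO:0006909
name: phagocytosis
namespace: biological_process
is_a: GO:0002376 ! immune system process

[Term]
id: GO:0008063
name: Toll signaling pathway
namespace: biological_process
is_a: GO:0045087 ! innate immune response

[Term]
id: GO:0009253
name: peptidoglycan catabolic process
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0006749
name: glutathione metabolic process
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0006631
name: fatty acid metabolic process
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0098754
name: detoxification
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0006979
name: response to oxidative stress
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0016070
name: RNA metabolic process
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0006412
name: translation
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0006486
name: protein glycosylation
namespace: biological_process
is_a: GO:0008152 ! metabolic process

[Term]
id: GO:0016337
name: single organismal cell-cell adhesion
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0007165
name: signal transduction
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0003824
name: catalytic activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0016740
name: transferase activity
namespace: molecular_function
is_a: GO:0003824 ! catalytic activity

[Term]
id: GO:0016787
name: hydrolase activity
namespace: molecular_function
is_a: GO:0003824 ! catalytic activity

[Term]
id: GO:0004364
name: glutathione transferase activity
namespace: molecular_function
is_a: GO:0016740 ! transferase activity

[Term]
id: GO:0003723
name: RNA binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0005488
name: binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0042834
name: peptidoglycan binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0003700
name: DNA-binding transcription factor activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0005575
name: cellular_component
namespace: cellular_component

[Term]
id: GO:0005622
name: intracellular anatomical structure
namespace: cellular_component
is_a: GO:0005575 ! cellular_component

[Term]
id: GO:0005737
name: cytoplasm
namespace: cellular_component
is_a: GO:0005622 ! intracellular anatomical structure

[Term]
id: GO:0005634
name: nucleus
namespace: cellular_component
is_a: GO:0005622 ! intracellular anatomical structure

[Term]
id: GO:0005840
name: ribosome
namespace: cellular_component
is_a: GO:0005737 ! cytoplasm

[Term]
id: GO:0005886
name: plasma membrane
namespace: cellular_component
is_a: GO:0005575 ! cellular_component
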