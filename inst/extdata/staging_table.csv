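# Staging calibration for Calliphora vicina embryogenesis, scored on living
# embryos at two constant temperatures (7.3 C and 25 C), eleven 10% intervals
# of total egg development (0% = oviposition, 100% = hatching).
# Symbols: blank = character not visible; + = visible in <25% of examined
# individuals; ++ = visible in 25-75%; +++ = visible in >75%.
# hwk_visible: character still scorable after hot water killing + 80% ethanol.
# Provenance notes (cells ambiguous in degraded renderings of the source table,
# resolved against the per-interval narrative descriptions):
#  - dorsal_folds at 7.3 C carries ++ (25 C carries +++) at the 30% interval.
#  - stomodeal_invagination at 7.3 C carries an extra + at the 30% interval.
#  - fully_developed_tracheal_system at 25 C is ++ (not +++) at 100%.
landmark_id,landmark_name,hwk_visible,temp_c,cat_0,cat_10,cat_20,cat_30,cat_40,cat_50,cat_60,cat_70,cat_80,cat_90,cat_100
homogeneous_yolk_mass,Homogeneous yolk mass,FALSE,7.3,++,,,,,,,,,,
homogeneous_yolk_mass,Homogeneous yolk mass,FALSE,25,++,,,,,,,,,,
clear_gaps,Clear gaps,FALSE,7.3,++,+++,,,,,,,,,
clear_gaps,Clear gaps,FALSE,25,++,+++,,,,,,,,,
bright_peripheral_ring,Bright peripheral ring,TRUE,7.3,,,+,,,,,,,,
bright_peripheral_ring,Bright peripheral ring,TRUE,25,,,+++,,,,,,,,
cephalic_furrow,Cephalic furrow,TRUE,7.3,,,+++,+++,,,,,,,
cephalic_furrow,Cephalic furrow,TRUE,25,,,+,+++,,,,,,,
dorsal_folds,Dorsal folds,FALSE,7.3,,,,++,,,,,,,
dorsal_folds,Dorsal folds,FALSE,25,,,,+++,,,,,,,
stomodeal_invagination,Stomodeal invagination,TRUE,7.3,,,,+,+++,+++,+++,+++,,,
stomodeal_invagination,Stomodeal invagination,TRUE,25,,,,,+++,+++,+++,+++,,,
thoracic_segmentation,Thoracic segmentation,TRUE,7.3,,,,,+,+++,+++,+++,+++,+++,+++
thoracic_segmentation,Thoracic segmentation,TRUE,25,,,,,+,+++,+++,+++,+++,+++,+++
clypeolabrum,Clypeolabrum,TRUE,7.3,,,,,,+++,+++,+++,,,
clypeolabrum,Clypeolabrum,TRUE,25,,,,,+,+++,+++,+++,,,
abdominal_segmentation,Abdominal segmentation,TRUE,7.3,,,,,,++,+++,+++,+++,+++,+++
abdominal_segmentation,Abdominal segmentation,TRUE,25,,,,,,+,+++,+++,+++,+++,+++
sack_shaped_gut,Sack-shaped gut,TRUE,7.3,,,,,,,,+++,,,
sack_shaped_gut,Sack-shaped gut,TRUE,25,,,,,,,,+++,,,
coil_shaped_gut,Coil-shaped gut,TRUE,7.3,,,,,,,,+,+++,+++,+++
coil_shaped_gut,Coil-shaped gut,TRUE,25,,,,,,,,,+++,+++,+++
spine_bands,Spine bands,TRUE,7.3,,,,,,,,,,+++,+++
spine_bands,Spine bands,TRUE,25,,,,,,,,,,+++,+++
posterior_spiracles,Posterior spiracles,TRUE,7.3,,,,,,,,,,+++,+++
posterior_spiracles,Posterior spiracles,TRUE,25,,,,,,,,,,+++,+++
cephalopharyngeal_skeleton,Cephalopharyngeal skeleton,TRUE,7.3,,,,,,,,,,,+++
cephalopharyngeal_skeleton,Cephalopharyngeal skeleton,TRUE,25,,,,,,,,,,+,+++
fully_developed_tracheal_system,Fully developed tracheal system,FALSE,7.3,,,,,,,,,,,+++
fully_developed_tracheal_system,Fully developed tracheal system,FALSE,25,,,,,,,,,,,++
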