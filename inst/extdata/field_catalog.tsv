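name	source	data_format	technology	field_class	sage_only	table_delimiter	duplicate
characteristics	documented	semi_structured	both	biological	FALSE	FALSE	FALSE
description	documented	unstructured	both	biological	FALSE	FALSE	FALSE
growth_protocol	documented	unstructured	both	biological	FALSE	FALSE	FALSE
molecule	documented	structured	both	biological	FALSE	FALSE	FALSE
organism	documented	structured	both	biological	FALSE	FALSE	FALSE
source_name	documented	unstructured	both	biological	FALSE	FALSE	FALSE
treatment_protocol	documented	unstructured	both	biological	FALSE	FALSE	FALSE
contact_city	documented	structured	both	database	FALSE	FALSE	FALSE
contact_department	documented	structured	both	database	FALSE	FALSE	FALSE
contact_email	documented	structured	both	database	FALSE	FALSE	FALSE
contact_fax	documented	structured	both	database	FALSE	FALSE	FALSE
contact_institute	documented	structured	both	database	FALSE	FALSE	FALSE
contact_name	documented	structured	both	database	FALSE	FALSE	FALSE
contact_phone	documented	structured	both	database	FALSE	FALSE	FALSE
contact_web_link	documented	structured	both	database	FALSE	FALSE	FALSE
data_row_count	documented	structured	both	database	FALSE	FALSE	FALSE
geo_accession	documented	structured	both	database	FALSE	FALSE	FALSE
last_update_date	documented	structured	both	database	FALSE	FALSE	FALSE
status	documented	structured	both	database	FALSE	FALSE	FALSE
submission_date	documented	structured	both	database	FALSE	FALSE	FALSE
title	documented	unstructured	both	database	FALSE	FALSE	FALSE
biomaterial_provider	documented	structured	both	technical	FALSE	FALSE	FALSE
channel_count	documented	structured	both	technical	FALSE	FALSE	FALSE
data_processing	documented	unstructured	both	technical	FALSE	FALSE	FALSE
extract_protocol	documented	unstructured	both	technical	FALSE	FALSE	FALSE
hyb_protocol	documented	unstructured	microarray	technical	FALSE	FALSE	FALSE
label	documented	structured	microarray	technical	FALSE	FALSE	FALSE
label_protocol	documented	unstructured	microarray	technical	FALSE	FALSE	FALSE
platform_id	documented	structured	both	technical	FALSE	FALSE	FALSE
scan_protocol	documented	unstructured	microarray	technical	FALSE	FALSE	FALSE
supplementary_file	documented	structured	both	technical	FALSE	FALSE	FALSE
type	documented	structured	both	technical	FALSE	FALSE	FALSE
taxid	reported_in_study	structured	both	biological	FALSE	FALSE	FALSE
contact_address	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
contact_country	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
contact_laboratory	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
contact_state	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
contact_zip/postal_code	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
relation	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
series_id	reported_in_study	structured	both	database	FALSE	FALSE	FALSE
barcode	reported_in_study	structured	rnaseq	technical	FALSE	FALSE	FALSE
instrument_model	reported_in_study	structured	rnaseq	technical	FALSE	FALSE	FALSE
library_selection	reported_in_study	structured	rnaseq	technical	FALSE	FALSE	FALSE
library_source	reported_in_study	structured	rnaseq	technical	FALSE	FALSE	FALSE
library_strategy	reported_in_study	structured	rnaseq	technical	FALSE	FALSE	FALSE
anchor	documented	structured	both	technical	TRUE	FALSE	FALSE
tag_count	documented	structured	both	technical	TRUE	FALSE	FALSE
tag_length	documented	structured	both	technical	TRUE	FALSE	FALSE
table_begin	documented	structured	both	technical	FALSE	TRUE	FALSE
table	documented	structured	both	technical	FALSE	TRUE	FALSE
table_end	documented	structured	both	technical	FALSE	TRUE	FALSE
geo_accession	documented	structured	both	database	FALSE	FALSE	TRUE
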