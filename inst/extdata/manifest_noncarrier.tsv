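sample_id	cohort
UTSW1	nonBRCA
UTSW2	nonBRCA
UTSW3	nonBRCA
UTSW4	nonBRCA
UTSW5	nonBRCA
UTSW6	nonBRCA
UTSW7	nonBRCA
UTSW8	nonBRCA
UTSW9	nonBRCA
UTSW10	nonBRCA
UTSW11	nonBRCA
UTSW12	nonBRCA
UTSW13	nonBRCA
UTSW14	nonBRCA
UTSW15	nonBRCA
UTSW16	nonBRCA
UTSW17	nonBRCA
UTSW18	nonBRCA
UTSW19	nonBRCA
UTSW20	nonBRCA
UTSW21	nonBRCA
UTSW22	nonBRCA
UTSW23	nonBRCA
UTSW24	nonBRCA
UTSW25	nonBRCA
UTSW26	nonBRCA
UTSW27	nonBRCA
UTSW28	nonBRCA
UTSW29	nonBRCA
UTSW30	nonBRCA
UTSW31	nonBRCA
UTSW32	nonBRCA
UTSW33	nonBRCA
UTSW34	nonBRCA
UTSW35	nonBRCA
UTSW36	nonBRCA
UTSW37	nonBRCA
UTSW38	nonBRCA
UTSW39	nonBRCA
UTSW40	nonBRCA
UTSW41	nonBRCA
UTSW42	nonBRCA
UTSW43	nonBRCA
UTSW44	nonBRCA
UTSW45	nonBRCA
UTSW46	nonBRCA
UTSW47	nonBRCA
UTSW48	nonBRCA
UTSW49	nonBRCA
UTSW50	nonBRCA
UTSW51	nonBRCA
UTSW52	nonBRCA
UTSW53	nonBRCA
UTSW54	nonBRCA
UTSW55	nonBRCA
UTSW56	nonBRCA
UTSW57	nonBRCA
UTSW58	nonBRCA
UTSW59	nonBRCA
UTSW60	nonBRCA
UTSW61	nonBRCA
UTSW62	nonBRCA
UTSW63	nonBRCA
UTSW64	nonBRCA
UTSW65	nonBRCA
UTSW66	nonBRCA
UTSW67	nonBRCA
UTSW68	nonBRCA
UTSW69	nonBRCA
UTSW70	nonBRCA
UTSW71	nonBRCA
UTSW72	nonBRCA
UTSW73	nonBRCA
UTSW74	nonBRCA
UTSW75	nonBRCA
UTSW76	nonBRCA
UTSW77	nonBRCA
UTSW78	nonBRCA
UTSW79	nonBRCA
UTSW80	nonBRCA
UTSW81	nonBRCA
UTSW82	nonBRCA
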