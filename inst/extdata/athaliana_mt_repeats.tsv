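name	copy1	copy2	percent_id	length
A	19,682-20,237	346,208-346,763	99.82	556
L	270,775-271,023	331,877-332,125	100	249
EE	65,547-65,673	73,611-73,737	99.21	127
F	206,095-206,444	246,766-247,115	100	350
B	41,464-41,999	321,967-321,431	99.81	536
D	6,118-6,569	84,540-84,089	97.79	452
C	36,362-36,824	144,409-143,947	99.57	463
X	288,315-288,518	306,969-307,174	97.57	204
I	30,442-30,722	255,122-254,842	99.64	281
MMJS	134,427-135,193	257,452-258,143	88.66	767
Unnamed	239,143-239,268	263,789-263,905	91.27	126
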