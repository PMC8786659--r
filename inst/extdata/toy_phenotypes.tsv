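sample_id	code	source	age_at_event
P01	CHD001	hospital-episode	12
P02	AVD001	hospital-episode	58
P03	AVD002	primary-care	64
P04	AVD001	hospital-episode	65
P05	AVD003	hospital-episode	72
P06	NEU001	primary-care	55
P07	EXC001	hospital-episode	60
P08	CHD002	hospital-episode	3
P08	AVD001	hospital-episode	70
P09	AVD002	hospital-episode
P10	CHD003	primary-care	1
P10	NEU002	primary-care	66
P11	ZZZ999	primary-care	50
P12	AVD001	hospital-episode	40
P12	AVD003	hospital-episode	68
P13	EXC001	hospital-episode	45
P13	AVD002	hospital-episode	65
P14	NEU001	hospital-episode	62
P14	NEU002	primary-care	64
P15	AVD003	primary-care	64
P16	CHD001	hospital-episode	30
P16	EXC001	hospital-episode	44
P17	ZZZ999	hospital-episode	20
P17	AVD001	primary-care	66
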